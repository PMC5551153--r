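active_ingredient,moa_class,deposit_ul_cm2,label_warnings
chlorpyrifos,contact,3.41,
mineral oil,suffocating,4.72,
paraffin oil,suffocating,4.72,
pyriproxyfen,contact,3.41,
abamectin,contact,3.41,
spirodiclofen,contact,3.41,
spirotetramat,contact,3.41,
etoxazole,contact,3.41,
tetrazine,contact,3.41,
clofentezine,contact,3.41,
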