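cultivar,cultivar_group
Owari,low
Okitsu,low
Fino,low
Clemenules,medium
Marisol,medium
Oronules,medium
Nadorcott,medium
Nova,medium
Orri,medium
Washington,medium
Lane late,medium
Fortune,high
Garbi,high
Moncada,high
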