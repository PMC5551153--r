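# Random but plausible orchard geometries for property tests.
random_geometry <- function() {
  orchard_geometry(
    h = runif(1, 1.5, 4),
    d_across = runif(1, 2, 6),
    d_along = runif(1, 1.5, 6),
    sp_tree = runif(1, 2, 7),
    sp_row = runif(1, 4, 8)
  )
}

# geometry of trial orchard P1 (Clemenules, 6 x 3 m frame)
p1_geometry <- function() {
  orchard_geometry(h = 2.51, d_across = 4.33, d_along = 3.08,
                   sp_tree = 3, sp_row = 6)
}
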