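## Constructed 7-link conformation pair whose ghost transformation
## self-crosses exactly twice: only beads 3 and 8 move (in z only, so
## every link projection is constant in the XY plane), bead 8 carries
## link 7 through link 5 first (it starts furthest), and bead 3 carries
## link 2 through link 4 later.  Crossing z-passages are placed off the
## delta = 0.02 step grid.
two_crossing_coords <- list(
  a = rbind(c(0.0,  0.0,  0.00),
            c(1.0,  0.0,  0.00),
            c(2.0,  1.0,  1.03),
            c(1.0,  1.0,  0.00),
            c(2.0,  0.0,  0.00),
            c(3.0,  0.0,  0.00),
            c(2.5,  1.0,  0.00),
            c(2.5, -1.0, -0.53)),
  b = rbind(c(0.0,  0.0,  0.00),
            c(1.0,  0.0,  0.00),
            c(2.0,  1.0, -0.97),
            c(1.0,  1.0,  0.00),
            c(2.0,  0.0,  0.00),
            c(3.0,  0.0,  0.00),
            c(2.5,  1.0,  0.00),
            c(2.5, -1.0,  2.47)))
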