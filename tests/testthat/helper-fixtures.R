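# Shared fixtures built in code.

# regular 10 Hz trace from channel vectors (pads/validates via tag_trace)
make_trace <- function(speed, depth = NULL, pitch = NULL, gyro = NULL,
                       fs = 10) {
  n <- length(speed)
  t <- seq(0, by = 1 / fs, length.out = n)
  tag_trace(t,
            depth %||% rep(50, n),
            pitch %||% rep(0, n),
            speed,
            gyro %||% rep(0, n),
            sample_rate = fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reference morphometric record used across engulfment/energetics tests
ref_morph <- function(species = "blue") {
  ref <- species_reference()
  r <- ref[ref$species == species, ]
  Wbz <- c(minke = 1.10, humpback = 1.63, fin = 2.20, blue = 2.90)[[species]]
  Lrbh <- c(minke = 2.09, humpback = 3.93, fin = 4.33, blue = 5.14)[[species]]
  complete_morphometrics(paste0(species, "_ref"), species,
                         L_body = r$L_body, w_max = 0.13 * r$L_body,
                         W_bz = Wbz, L_rbh = Lrbh,
                         A_jaw_direct = r$A_jaw_direct)
}
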