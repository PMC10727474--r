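# Independent oracles and small fixture builders used across the suite.

# brute-force O(N^2 K^2) clipped convolution: the reference for field checks
naive_convolve <- function(mask, weights) {
  nr <- nrow(mask); nc <- ncol(mask)
  rad <- (nrow(weights) - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc]) next
    for (di in -rad:rad) for (dj in -rad:rad) {
      rr <- r + di; c2 <- cc + dj
      if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc)
        out[rr, c2] <- out[rr, c2] + weights[di + rad + 1L, dj + rad + 1L]
    }
  }
  out
}

# a small implant geometry that keeps test runs fast
tiny_geometry <- function() geometry_config(20L, 20L, ring = 10L, hole_w = 6L, hole_h = 3L)

tiny_lattice <- function(fill = "HT_NO_WARBURG") {
  make_initial(scenario(fill), tiny_geometry())
}

uniform_lattice <- function(archetype, w = 10L, h = 10L) {
  make_lattice(w, h, make_archetype(archetype))
}

zero_field <- function(w = 1L, h = 1L) {
  f <- lapply(factor_ids(), function(i) matrix(0, h, w))
  names(f) <- factor_ids()
  f
}

local_conc <- function(gf1 = 0, gf2 = 0, gf3 = 0, lactate = 0) {
  c(GF1 = gf1, GF2 = gf2, GF3 = gf3, LACTATE = lactate)
}
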