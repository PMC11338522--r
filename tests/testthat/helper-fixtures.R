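# Small builders shared across the suite. Everything is generated in code;
# no stored fixtures.

tiny_image <- function(values, nrow, ncol, px = 20) {
  pixel_image(matrix(values, nrow, ncol), pixel_size_nm = px)
}

tiny_scene <- function(length_um = 5, width_nm = 400, n_puncta = 50,
                       bound_fraction = 0.5, bind_nm = 30, r_nm = 80,
                       seed = 1, ...) {
  make_scene(make_axon_trace(length_um, width_nm = width_nm, seed = seed),
             n_puncta = n_puncta, bound_fraction = bound_fraction,
             bind_distance_nm = bind_nm, er_tubule_radius_nm = r_nm,
             seed = seed, ...)
}

# strip everything but dim: bare matrix for exact comparisons
bare <- function(x) array(as.vector(unclass(x)), dim = dim(x))

# brute-force oracle: per-pixel dilation by a disk of radius r_px
brute_dilate <- function(m, r_px) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (di in -r_px:r_px) for (dj in -r_px:r_px) {
      if (di^2 + dj^2 > r_px^2) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && m[ii, jj]) {
        out[i, j] <- TRUE
      }
    }
  }
  out
}

# brute-force oracle: intensity fraction inside mask, elementwise loop
brute_fraction <- function(img, mask) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    den <- den + img[i, j]
    if (mask[i, j]) num <- num + img[i, j]
  }
  num / den
}
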