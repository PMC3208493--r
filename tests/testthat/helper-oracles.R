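# Independent brute-force GLEM oracle: loops over every mask-true pixel and
# recomputes its windowed histogram and entropy from first principles.
glem_oracle <- function(pixels, mask, w = 9, G = 64, B = 64,
                        emax = log2(G)) {
  counts <- matrix(0, G, B)
  emap <- matrix(NA_real_, nrow(pixels), ncol(pixels))
  half <- w %/% 2
  for (r in seq_len(nrow(pixels))) {
    for (cc in seq_len(ncol(pixels))) {
      if (!mask[r, cc]) next
      rows <- max(1, r - half):min(nrow(pixels), r + half)
      cols <- max(1, cc - half):min(ncol(pixels), cc + half)
      v <- pixels[rows, cols][mask[rows, cols]]
      p <- as.numeric(table(v)) / length(v)
      H <- -sum(p * log2(p))
      j <- min(floor(H * B / emax), B - 1)
      counts[pixels[r, cc] + 1, j + 1] <- counts[pixels[r, cc] + 1, j + 1] + 1
      emap[r, cc] <- H
    }
  }
  list(P = counts / sum(counts), entropy_map = emap)
}

# Quick constructor for hand-built nuclei.
make_nucleus <- function(pixels, mask = matrix(TRUE, nrow(pixels),
                                               ncol(pixels)),
                         grey_depth = 1024L, ...) {
  nucleus_image(pixels, mask, grey_depth = grey_depth, ...)
}

# Minimal glem_set for feature-level tests: arbitrary probability matrices
# standing in for nuclear GLEMs.
make_glem_set <- function(info, glems) {
  structure(list(info = info, glems = glems), class = "glem_set")
}

# Hand-built discriminant container.
make_disc <- function(groups, epsilon = 1e-8) {
  structure(list(groups = groups, epsilon = epsilon),
            class = "nt_discriminants")
}
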