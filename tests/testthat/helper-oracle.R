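# Naive pair-enumeration GLCM: loops over every pixel and every (i, j) cell.
# Independent of the vectorized implementation; used as the ground truth.
oracle_glcm <- function(m, G, d, angle, symmetric) {
  disp <- switch(as.character(angle),
                 "0" = c(0, d), "45" = c(-d, d),
                 "90" = c(-d, 0), "135" = c(-d, -d))
  C <- matrix(0, G, G)
  n <- 0
  for (r in seq_len(nrow(m))) {
    for (cc in seq_len(ncol(m))) {
      r2 <- r + disp[1]; c2 <- cc + disp[2]
      if (r2 >= 1 && r2 <= nrow(m) && c2 >= 1 && c2 <= ncol(m)) {
        i <- m[r, cc] + 1; j <- m[r2, c2] + 1
        C[i, j] <- C[i, j] + 1
        n <- n + 1
        if (symmetric) {
          C[j, i] <- C[j, i] + 1
          n <- n + 1
        }
      }
    }
  }
  C / n
}

oracle_features <- function(C, base = 2) {
  G <- nrow(C)
  out <- c(contrast = 0, energy = 0, homogeneity = 0, entropy = 0)
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      p <- C[i, j]
      out["contrast"] <- out["contrast"] + p * (i - j)^2
      out["energy"] <- out["energy"] + p^2
      out["homogeneity"] <- out["homogeneity"] + p / (1 + abs(i - j))
      if (p > 0) out["entropy"] <- out["entropy"] - p * log(p, base)
    }
  }
  out
}

random_patch <- function(side, G) {
  gray_patch(matrix(sample(0:(G - 1), side^2, replace = TRUE), side, side), G)
}

# small study shared by group-stat and synthetic tests
small_study_features <- function(n = 6, seed = 11) {
  ds <- generate_study(n, seed = seed)
  study_feature_table(ds)
}
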