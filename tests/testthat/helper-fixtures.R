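# shared fixtures and small independent oracles

# lightness image with k dark discs (L = l_disc) on a bright background
# (L = l_bg); returns the L matrix and the exact disc pixel count
disc_lightness <- function(nr, nc, centers, radius_px, l_disc = 20,
                           l_bg = 95) {
  L <- matrix(l_bg, nr, nc)
  for (i in seq_len(nrow(centers))) {
    rows <- pmax(1, floor(centers[i, 1] - radius_px)):
      pmin(nr, ceiling(centers[i, 1] + radius_px))
    cols <- pmax(1, floor(centers[i, 2] - radius_px)):
      pmin(nc, ceiling(centers[i, 2] + radius_px))
    for (r in rows) {
      inside <- (r - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
        radius_px^2
      L[r, cols[inside]] <- l_disc
    }
  }
  list(L = L, n_disc_px = sum(L == l_disc))
}

# adjusted Rand index (closed form over the contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  (si - e) / ((sa + sb) / 2 - e)
}

# area under the ROC curve via the rank-sum statistic
auc <- function(score, positive) {
  ok <- is.finite(score)
  score <- score[ok]; positive <- positive[ok]
  r <- rank(score)
  np <- sum(positive); nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# two planted linear compartments in (cellularity, luminal fraction, sADC),
# the planted slopes being the package-wide reference gradients
two_plane_triples <- function(n_per = 1000, noise_frac = 0.05, seed = 33,
                              slopes = c(-7.0e-6, -8.2e-6),
                              intercepts = c(0.30, 0.18),
                              lf_slope = 1e-4) {
  withr::with_seed(seed, {
    mk <- function(n, int, slc) {
      C <- runif(n, 0, 12000)
      lf <- runif(n, 0, 60)
      y <- int + slc * C + lf_slope * lf
      y <- y + rnorm(n, 0, noise_frac * mean(abs(y)))
      data.frame(cellularity = C, luminal_fraction = lf, sadc = y)
    }
    d1 <- mk(n_per, intercepts[1], slopes[1])
    d2 <- mk(n_per, intercepts[2], slopes[2])
    d1$component <- 1L
    d2$component <- 2L
    rbind(d1, d2)
  })
}

# small synthetic tissue shared by several tests (cached per session)
shared_tissue <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_tissue(tissue_spec(
        image_size_px = c(1000L, 1000L), target_cellularity = 4000,
        target_luminal_fraction = 30, seed = 11L))
    }
    cache
  }
})
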