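test_that("filter tables hold the standard analysis pairs", {
  h <- wavelet_filters("haar")
  expect_equal(abs(h$dec_lo), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(sort(h$dec_hi), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  d4 <- wavelet_filters("db4")
  expect_length(d4$dec_lo, 8L)
  expect_length(d4$dec_hi, 8L)
  expect_equal(sum(d4$dec_lo^2), 1, tolerance = 1e-10)

  for (fam in c("haar", "db2", "db4", "sym4", "coif2", "coif3")) {
    f <- wavelet_filters(fam)
    expect_true(f$orthogonal)
    expect_equal(sum(f$dec_lo^2), 1, tolerance = 1e-10)
    # analysis pair is orthogonal: high-pass also unit norm, zero dot product
    expect_equal(sum(f$dec_hi^2), 1, tolerance = 1e-10)
    expect_equal(sum(f$dec_lo * f$dec_hi), 0, tolerance = 1e-10)
  }
  expect_false(wavelet_filters("bior3.5")$orthogonal)
  expect_error(wavelet_filters("db99"), "unsupported wavelet family")
})

test_that("single-level decomposition matches closed-form Haar cases", {
  spec <- wavelet_spec("haar")
  q <- dwt2_single(matrix(1, 4, 4), spec)
  expect_equal(as.vector(q$ll), rep(2, 4), tolerance = 1e-12)
  expect_equal(max(abs(c(q$lh, q$hl, q$hh))), 0, tolerance = 1e-12)

  x <- matrix(c(1.5, -2, 0.5, 3), 2, 2, byrow = TRUE)  # [[a,b],[c,d]]
  a <- 1.5; b <- -2; c <- 0.5; d <- 3
  q <- dwt2_single(x, spec)
  # high-pass taps are (-1, 1)/sqrt(2), the standard analysis orientation
  expect_equal(as.vector(q$ll), (a + b + c + d) / 2, tolerance = 1e-12)
  expect_equal(as.vector(q$lh), (-a + b - c + d) / 2, tolerance = 1e-12)
  expect_equal(as.vector(q$hh), (a - b - c + d) / 2, tolerance = 1e-12)
  expect_equal(as.vector(q$hl), (-a - b + c + d) / 2, tolerance = 1e-12)
})

test_that("odd dimensions are edge-padded and all bands are ceiling-sized", {
  set.seed(3)
  x <- matrix(rnorm(25), 5, 5)
  for (fam in c("haar", "db2", "sym4")) {
    q <- dwt2_single(x, wavelet_spec(fam))
    o <- naive_dwt2(x, fam)
    expect_equal(dim(q$ll), c(3L, 3L))
    for (band in c("ll", "lh", "hl", "hh"))
      expect_equal(q[[band]], o[[band]], tolerance = 1e-10)
  }
})

test_that("decomposition validates its input", {
  spec <- wavelet_spec("haar")
  expect_error(dwt2_single(matrix(1, 1, 5), spec), "too small")
  x <- matrix(1, 4, 4); x[2, 2] <- NA
  expect_error(dwt2_single(x, spec), "non-finite")
  expect_error(wavelet_spec("haar", levels = 0), "positive integer")
})

test_that("sub-band energies follow the selected convention", {
  q <- dwt2_single(matrix(1, 4, 4), wavelet_spec("haar"))
  for (mode in c("raw-mean", "abs-mean", "squared-mean")) {
    e <- subband_energy(q, mode)
    expect_equal(unname(e["LL"]), if (mode == "squared-mean") 4 else 2)
    expect_equal(unname(e[c("LH", "HL", "HH")]), rep(0, 3), tolerance = 1e-12)
  }

  # sign cancellation: zero-mean alternating band has raw-mean 0, abs-mean 1
  q2 <- q
  q2$lh <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(unname(subband_energy(q2, "raw-mean")["LH"]), 0)
  expect_equal(unname(subband_energy(q2, "abs-mean")["LH"]), 1)

  # brute-force double-loop oracle on random integer bands
  set.seed(11)
  q3 <- q
  for (band in c("ll", "lh", "hl", "hh"))
    q3[[band]] <- matrix(sample(-9:9, 9, replace = TRUE), 3, 3)
  brute <- function(m, f) {
    s <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) s <- s + f(m[i, j])
    s / (nrow(m) * ncol(m))
  }
  expect_equal(unname(subband_energy(q3, "raw-mean")),
               sapply(list(q3$ll, q3$lh, q3$hl, q3$hh), brute, f = identity))
  expect_equal(unname(subband_energy(q3, "abs-mean")),
               sapply(list(q3$ll, q3$lh, q3$hl, q3$hh), brute, f = abs))
  expect_equal(unname(subband_energy(q3, "squared-mean")),
               sapply(list(q3$ll, q3$lh, q3$hl, q3$hh), brute,
                      f = function(v) v^2))
})

test_that("dominant sub-band selection uses energy argmax with LL-first ties", {
  spec <- wavelet_spec("haar")
  expect_equal(dominant_subband(dwt2_single(matrix(2, 6, 6), spec))$label, "LL")

  # all-zero input: four equal energies, precedence picks LL
  expect_equal(dominant_subband(dwt2_single(matrix(0, 4, 4), spec))$label, "LL")

  # fine checkerboard: diagonal detail dominates under abs-mean
  ch <- outer(1:8, 1:8, function(i, j) (-1)^(i + j))
  dom <- dominant_subband(dwt2_single(ch, spec), "abs-mean")
  o <- naive_dwt2(ch, "haar")
  eo <- sapply(o, function(m) mean(abs(m)))
  expect_equal(dom$label, "HH")
  expect_equal(names(which.max(eo)), "hh")
})

test_that("the transform is linear and preserves energy for orthogonal families", {
  set.seed(7)
  for (fam in c("haar", "db2", "sym4")) {
    spec <- wavelet_spec(fam)
    for (rep in 1:5) {
      x <- matrix(rnorm(48), 6, 8); y <- matrix(rnorm(48), 6, 8)
      a <- rnorm(1); b <- rnorm(1)
      qa <- dwt2_single(a * x + b * y, spec)
      qx <- dwt2_single(x, spec); qy <- dwt2_single(y, spec)
      for (band in c("ll", "lh", "hl", "hh"))
        expect_equal(qa[[band]], a * qx[[band]] + b * qy[[band]],
                     tolerance = 1e-8)
    }
  }
  for (fam in c("haar", "db2", "db4", "sym4", "coif2", "coif3")) {
    x <- matrix(rnorm(144), 12, 12)
    q <- dwt2_single(x, wavelet_spec(fam))
    expect_equal(sum(q$ll^2) + sum(q$lh^2) + sum(q$hl^2) + sum(q$hh^2),
                 sum(x^2), tolerance = 1e-6)
  }
})

test_that("operator implementation matches the naive reference on small inputs", {
  set.seed(5)
  fams <- c("haar", "db2", "db4", "sym4", "coif2", "coif3", "bior3.5")
  for (rep in 1:100) {
    h <- sample(2:6, 1); w <- sample(2:6, 1)
    x <- matrix(sample(-3:3, h * w, replace = TRUE), h, w)
    fam <- fams[(rep - 1) %% length(fams) + 1]
    q <- dwt2_single(x, wavelet_spec(fam))
    o <- naive_dwt2(x, fam)
    expect_equal(dim(q$ll), c(ceiling(h / 2), ceiling(w / 2)))
    for (band in c("ll", "lh", "hl", "hh"))
      expect_equal(q[[band]], o[[band]], tolerance = 1e-10)
  }
})

test_that("multi-channel input keeps channels independent", {
  set.seed(9)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  q <- dwt2_single(x, wavelet_spec("db2"))
  expect_equal(dim(q$ll), c(2L, 2L, 3L))
  for (c in 1:3) {
    qc <- dwt2_single(x[, , c], wavelet_spec("db2"))
    expect_equal(q$ll[, , c], qc$ll, tolerance = 1e-12)
    expect_equal(q$hh[, , c], qc$hh, tolerance = 1e-12)
  }
  # channel-averaged energy
  expect_equal(unname(subband_energy(q)["LL"]), mean(q$ll), tolerance = 1e-12)
})
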