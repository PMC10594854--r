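fake_counts <- function(counts, k, taxon_id = "fake") {
  structure(
    list(k = as.integer(k), taxon_id = taxon_id,
         counts = as.integer(counts), total_windows = sum(counts)),
    class = "kmer_counts"
  )
}

fv_from_ranks <- function(ranks, set, taxon_id = "x",
                          tie_policy = "ordinal") {
  structure(list(taxon_id = taxon_id, set = set, tie_policy = tie_policy,
                 ranks = ranks),
            class = "feature_vector")
}

test_that("feature-set presets have the documented sizes", {
  expect_equal(build_feature_set(8, "CG12")$size, 24991)
  expect_equal(build_feature_set(8, "TA12")$size, 24991)
  expect_equal(build_feature_set(8, "CG0")$size, 40545)
  expect_equal(build_feature_set(8, "TOTAL")$size, 65536)
  custom <- build_feature_set(8, list(xy = "CG", classes = c(1, 2)))
  expect_equal(custom$members, build_feature_set(8, "CG12")$members)
  expect_error(build_feature_set(8, "XZ99"), "unknown feature set")
  s <- build_feature_set(4, "CG12")
  expect_true(all(diff(s$members) > 0))
  expect_true(all(s$members >= 0 & s$members < 4^4))
})

test_that("relative frequency ranks ascend with counts", {
  set <- build_feature_set(2, "CG12")  # single member at k=2: just CG
  expect_equal(set$size, 1L)
  set3 <- build_feature_set(2, list(xy = "CG", classes = 0))  # 15 members
  counts <- rep(0L, 16)
  counts[encode_kmer("AA") + 1] <- 5L
  counts[encode_kmer("AC") + 1] <- 2L
  counts[encode_kmer("AG") + 1] <- 9L
  fv <- relative_frequency(fake_counts(counts, 2), set3)
  named <- setNames(fv$ranks, sapply(set3$members, decode_kmer, k = 2))
  expect_equal(unname(named["AC"]) > unname(named["AA"]), FALSE)
  expect_equal(unname(named["AG"]), 15)   # largest count -> top rank
  expect_equal(unname(named["AA"]), 14)
  expect_equal(unname(named["AC"]), 13)
})

test_that("ordinal ties break by ascending k-mer index; average ties share", {
  set <- build_feature_set(2, list(xy = "CG", classes = 0))
  counts <- rep(0L, 16)
  counts[encode_kmer("AA") + 1] <- 4L  # index 0
  counts[encode_kmer("AC") + 1] <- 4L  # index 1
  counts[encode_kmer("AG") + 1] <- 1L
  cnt <- fake_counts(counts, 2)
  ord <- relative_frequency(cnt, set, "ordinal")
  expect_equal(sort(ord$ranks), 1:15)           # permutation of 1..N
  named <- setNames(ord$ranks, sapply(set$members, decode_kmer, k = 2))
  expect_equal(unname(named["AA"]), 14)          # tie: lower index first
  expect_equal(unname(named["AC"]), 15)
  expect_equal(unname(named["AG"]), 13)
  avg <- relative_frequency(cnt, set, "average")
  expect_equal(sum(avg$ranks), 15 * 16 / 2)      # rank mass conserved
  named_a <- setNames(avg$ranks, sapply(set$members, decode_kmer, k = 2))
  expect_equal(unname(named_a["AA"]), 14.5)
  expect_equal(unname(named_a["AC"]), 14.5)
})

test_that("ranks are invariant under strictly increasing count transforms", {
  set.seed(17)
  set <- build_feature_set(3, "CG12")
  for (rep in 1:10) {
    counts <- sample.int(50, 64, replace = TRUE) - 1L
    cnt <- fake_counts(counts, 3)
    f <- relative_frequency(cnt, set)
    mono <- fake_counts(as.integer(3L * counts + 7L), 3)
    expect_equal(relative_frequency(mono, set)$ranks, f$ranks)
    # a nonlinear strictly increasing transform
    sq <- fake_counts(as.integer(counts^2 + counts), 3)
    expect_equal(relative_frequency(sq, set)$ranks, f$ranks)
  }
})

test_that("pairwise distance is the RMSE of feature values", {
  set <- build_feature_set(2, list(xy = "CG", classes = 1))
  s3 <- structure(list(k = 2L, name = "toy", xy = NA, classes = NULL,
                       members = 0:2, size = 3L), class = "feature_set")
  a <- fv_from_ranks(c(1, 2, 3), s3)
  b <- fv_from_ranks(c(3, 2, 1), s3, taxon_id = "y")
  expect_equal(pairwise_distance(a, b), sqrt(8 / 3))
  expect_equal(pairwise_distance(a, a), 0)
  expect_equal(pairwise_distance(b, a), pairwise_distance(a, b))
  other <- fv_from_ranks(c(1, 2, 3), build_feature_set(2, "TOTAL"))
  expect_error(pairwise_distance(a, other), "different feature sets")
  avg <- fv_from_ranks(c(1, 2, 3), s3, tie_policy = "average")
  expect_error(pairwise_distance(a, avg), "tie policies")
})

test_that("distance satisfies metric axioms on random rank vectors", {
  set.seed(23)
  s <- structure(list(k = 4L, name = "toy", xy = NA, classes = NULL,
                      members = 0:19, size = 20L), class = "feature_set")
  for (rep in 1:20) {
    a <- fv_from_ranks(sample(20), s, "a")
    b <- fv_from_ranks(sample(20), s, "b")
    c_ <- fv_from_ranks(sample(20), s, "c")
    dab <- pairwise_distance(a, b)
    dbc <- pairwise_distance(b, c_)
    dac <- pairwise_distance(a, c_)
    expect_gte(dab, 0)
    expect_equal(dab == 0, identical(a$ranks, b$ranks))
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("max rank distance is sqrt((N^2-1)/3), attained by reversal", {
  for (N in 2:6) {
    perms <- as.matrix(expand.grid(rep(list(1:N), N)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == N), ,
                   drop = FALSE]
    d <- as.matrix(stats::dist(perms)) / sqrt(N)
    expect_equal(max(d), sqrt((N^2 - 1) / 3), tolerance = 1e-12,
                 label = paste0("N=", N))
    rev_d <- sqrt(sum((1:N - N:1)^2) / N)
    expect_equal(rev_d, sqrt((N^2 - 1) / 3), tolerance = 1e-12)
  }
})

test_that("distance_matrix is symmetric, zero-diagonal, input-ordered", {
  set.seed(29)
  set <- build_feature_set(3, "CG12")
  cs <- lapply(1:4, function(i)
    fake_counts(sample.int(30, 64, replace = TRUE) - 1L, 3,
                taxon_id = paste0("g", i)))
  fvs <- lapply(cs, relative_frequency, set = set)
  dm <- distance_matrix(fvs)
  expect_equal(rownames(dm), paste0("g", 1:4))
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 4))
  expect_equal(dm["g1", "g2"], pairwise_distance(fvs[[1]], fvs[[2]]))
  dup <- fvs; dup[[2]]$taxon_id <- "g1"
  expect_error(distance_matrix(dup), "duplicate taxon_id")
  # identical genomes give the zero matrix
  same <- lapply(1:3, function(i) {
    f <- fvs[[1]]; f$taxon_id <- paste0("s", i); f
  })
  expect_true(all(distance_matrix(same) == 0))
})

test_that("PHYLIP square matrix round-trips to written precision", {
  set.seed(31)
  n <- 5
  m <- matrix(stats::runif(n * n, 0, 10), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("tax", 1:n), paste0("tax", 1:n))
  p <- tempfile(fileext = ".phy")
  write_phylip(m, p)
  lines <- readLines(p)
  expect_equal(lines[1], "5")
  expect_length(lines, 6L)
  back <- read_phylip(p)
  expect_equal(rownames(back), rownames(m))
  expect_equal(back, m, tolerance = 1e-6)

  z <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  write_phylip(z, p)
  expect_true(all(grepl("0\\.000000", readLines(p)[-1])))

  bad <- m
  rownames(bad) <- colnames(bad) <- c("ok1", "has space", "ok3", "ok4", "ok5")
  expect_error(write_phylip(bad, p), "whitespace")
  writeLines(c("3", "a 0 0 0", "b 0 0 0"), p)
  expect_error(read_phylip(p), "row count mismatch")
  writeLines(c("x", "a 0"), p)
  expect_error(read_phylip(p), "malformed PHYLIP header")
})
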