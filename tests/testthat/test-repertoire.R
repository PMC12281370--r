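test_that("clonotype identity is (CDR3aa, V gene) with counts merged", {
  r <- repertoire(c("CASSA", "CASSA", "CASSB", "CASSA"),
                  c("TRBV9", "TRBV9", "TRBV9", "TRBV12"),
                  c(10, 5, 3, 2))
  expect_equal(richness(r), 3)  # CASSA/TRBV9 merged (15), CASSB, CASSA/TRBV12
  expect_equal(r$count[1], 15)
  expect_equal(sum(r$frequency), 1, tolerance = 1e-12)
  expect_error(repertoire(character(0), character(0), integer(0)), "empty")
  expect_error(repertoire("", "TRBV9", 1), "empty CDR3")
  expect_error(repertoire("CASSA", "TRBV9", 0), ">= 1")
})

test_that("entropy and clonality hit their closed-form anchors", {
  expect_equal(shannon_entropy(make_rep(rep(5, 4))), 2)        # log2 4
  expect_equal(shannon_entropy(make_rep(100)), 0)              # monoclonal
  expect_equal(clonality(make_rep(rep(3, 10))), 0)             # uniform
  expect_equal(clonality(make_rep(42)), 1)                     # n = 1 convention
  # frozen oracle values: term-by-term summation of (0.7, 0.1, 0.1, 0.1)
  f <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(shannon_entropy(f), 1.3567796494470394, tolerance = 1e-12)
  expect_equal(clonality(f), 0.3216101752764803, tolerance = 1e-12)
})

test_that("entropy, clonality and D50 match independent oracles on random repertoires", {
  set.seed(123)
  ent_oracle <- function(f) {        # explicit loop, no vectorized reuse
    h <- 0
    for (fi in f) if (fi > 0) h <- h - fi * log(fi) / log(2)
    h
  }
  d50_oracle <- function(f) {
    s <- sort(f, decreasing = TRUE)
    acc <- 0
    for (k in seq_along(s)) {
      acc <- acc + s[k]
      if (acc >= 0.5 - 1e-12) return(k)
    }
  }
  for (i in 1:1000) {
    f <- rand_freq(sample(1:60, 1))
    expect_equal(shannon_entropy(f), ent_oracle(f), tolerance = 1e-10)
    expect_identical(d50(f), d50_oracle(f))
    cl <- clonality(f)
    expect_gte(cl, -1e-12)
    expect_lte(cl, 1 + 1e-12)
    expect_lte(shannon_entropy(f), log2(length(f)) + 1e-10)
  }
})

test_that("D50 anchors: uniform, dominant clone, frozen mixed case", {
  expect_equal(d50(make_rep(rep(2, 10))), 5)
  expect_equal(d50(c(0.6, 0.2, 0.2)), 1)
  expect_equal(d50(c(0.3, 0.3, 0.2, 0.2)), 2)
  for (n in c(3, 7, 10, 25)) expect_equal(d50(rep(1 / n, n)), ceiling(n / 2))
})

test_that("expanding the largest clone never decreases clonality", {
  set.seed(77)
  for (i in 1:100) {
    f <- sort(rand_freq(sample(3:30, 1)), decreasing = TRUE)
    boost <- f; boost[1] <- boost[1] * 2
    boost <- boost / sum(boost)
    expect_gte(clonality(boost), clonality(f) - 1e-9)
  }
})

test_that("clone-size bins partition the frequency mass", {
  expect_equal(unname(clone_size_bins(c(1))["hyperexpanded"]), 1)
  small <- rep(1e-5, 1e5)
  expect_equal(unname(clone_size_bins(small)["small"]), 1, tolerance = 1e-9)
  # mixed fixture with hand-computed per-bin masses
  f <- c(0.5, 0.02, 0.005, 0.003, 0.0005, 0.0003, 0.00005)
  f <- c(f, 1 - sum(f))  # remainder 0.47115 -> hyperexpanded
  b <- clone_size_bins(f)
  expect_equal(unname(b["hyperexpanded"]), 0.5 + 0.02 + (1 - sum(f[1:7])))
  expect_equal(unname(b["large"]), 0.005 + 0.003)
  expect_equal(unname(b["medium"]), 0.0005 + 0.0003)
  expect_equal(unname(b["small"]), 0.00005)
  expect_equal(sum(b), 1, tolerance = 1e-9)
  set.seed(31)
  for (i in 1:50) expect_equal(sum(clone_size_bins(rand_freq(200))), 1,
                               tolerance = 1e-9)
})

test_that("overlap counts shared keys symmetrically", {
  a <- repertoire(paste0("C", 1:10), rep("TRBV9", 10), rep(2, 10))
  b <- repertoire(paste0("C", 4:15), rep("TRBV9", 12), rep(3, 12))
  expect_equal(overlap(a, b)$shared, 7)
  expect_equal(overlap(b, a)$shared, 7)
  expect_equal(overlap(a, a)$shared, richness(a))
  expect_equal(overlap(a, a)$jaccard, 1)
  disjoint <- repertoire(paste0("D", 1:5), rep("TRBV9", 5), rep(1, 5))
  expect_equal(overlap(a, disjoint)$shared, 0)
})

test_that("top-clonotype tracking reports per-sample frequencies", {
  ref <- repertoire(paste0("C", 1:6), rep("TRBV9", 6), c(60, 30, 20, 10, 5, 5))
  # within the reference itself the rows are the reference's own top-k
  m <- track_top(ref, list(ref = ref), k = 3)
  expect_equal(unname(m[, 1]), ref$frequency[1:3])
  s2 <- repertoire(c("C1", "C9"), c("TRBV9", "TRBV9"), c(1, 3))
  m2 <- track_top(ref, list(a = ref, b = s2), k = 2)
  expect_equal(unname(m2["C1|TRBV9", "b"]), 0.25)
  expect_equal(unname(m2["C2|TRBV9", "b"]), 0)   # absent clone reads 0
  expect_error(track_top(ref, list(ref), k = 10), "richness")
})

test_that("AIRR TSV and CSV dialects round-trip", {
  r <- make_rep(c(10, 5, 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_repertoire(r, tsv, "airr")
  write_repertoire(r, csv, "csv")
  for (p in c(tsv, csv)) {
    rr <- read_repertoire(p)
    expect_equal(rr$cdr3_aa, r$cdr3_aa)
    expect_equal(rr$count, r$count)
    expect_equal(rr$frequency, r$frequency)
  }
})

test_that("entropy agrees with an established ecology implementation", {
  skip_if_not_installed("vegan")
  set.seed(55)
  cnt <- sample(1:500, 40, replace = TRUE)
  r <- make_rep(cnt)
  expect_equal(shannon_entropy(r),
               as.numeric(vegan::diversity(cnt, index = "shannon")) / log(2),
               tolerance = 1e-10)
})
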