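test_that("confidence filtering is strict at the documented thresholds", {
  m <- function(id, ptm, iptm) {
    structure_model(id, "MAAA", matrix(rnorm(12), 4, 3), ptm, iptm)
  }
  set.seed(2)
  kept <- qc_filter(list(m("good", 0.6, 0.9), m("ptm_edge", 0.5, 0.9),
                         m("iptm_edge", 0.6, 0.8)))
  expect_equal(vapply(kept, function(x) x$model_id, ""), "good")
  expect_message(qc_filter(list(m("nometa", NA, NA))), "retained")
})

test_that("residue correspondence follows the sequence alignment", {
  set.seed(3)
  seq_a <- random_protein(60)
  coords <- matrix(rnorm(180), 60, 3)
  a <- structure_model("a", seq_a, coords)
  b <- structure_model("b", seq_a, coords)
  rc <- residue_correspondence(a, b)
  expect_equal(rc$idx_a, 1:60)
  expect_equal(rc$idx_b, 1:60)
  # one internal deletion is skipped in the mapping
  seq_del <- paste0(substr(seq_a, 1, 29), substr(seq_a, 36, 60))
  d <- structure_model("d", seq_del, coords[c(1:29, 36:60), ])
  rc2 <- residue_correspondence(a, d)
  expect_equal(nrow(rc2), 54)
  expect_false(any(30:35 %in% rc2$idx_a))
})

test_that("Kabsch RMSD is exact on closed-form and rigid-motion cases", {
  set.seed(5)
  a <- matrix(rnorm(60), 20, 3)
  expect_equal(kabsch_rmsd(a, a)$rmsd, 0)
  rot90z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_lt(kabsch_rmsd(a, a %*% t(rot90z))$rmsd, 1e-12)
  # analytic case: points at +-1 on x vs +-2 on x (duplicated to n = 4)
  pa <- matrix(c(1, 0, 0, 1, 0, 0, -1, 0, 0, -1, 0, 0), 4, 3, byrow = TRUE)
  pb <- 2 * pa
  expect_equal(kabsch_rmsd(pa, pb)$rmsd, 1)
  expect_error(kabsch_rmsd(a[1:2, ], a[1:2, ]), ">= 3")
})

test_that("RMSD is invariant under common rigid motions and symmetric", {
  set.seed(7)
  a <- matrix(rnorm(90), 30, 3)
  b <- a + matrix(rnorm(90, sd = 0.5), 30, 3)
  base <- kabsch_rmsd(a, b)$rmsd
  ang <- c(0.3, -1.2, 2.2)
  r <- paleodens:::euler_rotation(ang)
  shift <- matrix(c(10, -4, 7), 30, 3, byrow = TRUE)
  moved <- kabsch_rmsd(a %*% t(r) + shift, b %*% t(r) + shift)$rmsd
  expect_lt(abs(moved - base), 1e-9)
  expect_lt(abs(kabsch_rmsd(b, a)$rmsd - base), 1e-12)
})

test_that("Monte-Carlo noise recovery matches the recorded expectation", {
  set.seed(9)
  rmsds <- replicate(40, {
    sp <- make_structure_pair(200, perturb_sd = 1,
                              rotation = stats::runif(3, -pi, pi))
    kabsch_rmsd(sp$a, sp$b)$rmsd
  })
  sp <- make_structure_pair(200, perturb_sd = 1, seed = 1)
  expect_lt(abs(mean(rmsds) - sp$expected_rmsd) / sp$expected_rmsd, 0.1)
})

test_that("RMSD classes split at 2 and 3 angstroms inclusively", {
  expect_equal(as.character(classify_rmsd(0.271)), "highly_similar")
  expect_equal(as.character(classify_rmsd(2.0)), "highly_similar")
  expect_equal(as.character(classify_rmsd(2.446)), "moderately_similar")
  expect_equal(as.character(classify_rmsd(3.0)), "moderately_similar")
  expect_equal(as.character(classify_rmsd(3.001)), "significantly_divergent")
  expect_error(classify_rmsd(-0.1), "negative")
})

test_that("domain screening respects the distance cutoff and run pruning", {
  # linear chain at 3.8 A CA spacing
  n <- 30
  coords <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  m <- structure_model("chain", strrep("A", n), coords)
  got <- screen_domain(m, 15, cutoff = 5)
  expect_equal(got, 14:16)   # +-1 neighbour at 3.8 A, +-2 at 7.6 A
  expect_equal(screen_domain(m, 15, cutoff = 0), 15L)
  expect_equal(screen_domain(m, c(10, 20), cutoff = 5),
               c(9:11, 19:21))
  expect_error(screen_domain(m, integer(0)), "empty")
})

test_that("Walker-A seeds anchor the ATPase domain screen", {
  seq <- paste0(strrep("A", 10), "GPGNSGKST", strrep("A", 10))
  idx <- walker_a_seeds(seq)
  expect_equal(idx, 11:18)
  expect_equal(walker_a_seeds(strrep("A", 30)), integer(0))
})

test_that("structure comparison classifies global and domain RMSDs", {
  set.seed(11)
  sp <- make_structure_pair(120, perturb_sd = 0.5,
                            rotation = c(1, 0.2, -0.7),
                            translation = c(4, 4, 4), seed = 13)
  seq <- random_protein(120)
  a <- structure_model("a", seq, sp$a)
  b <- structure_model("b", seq, sp$b)
  res <- compare_structures(a, b, domains = list(core = 40:80))
  expect_equal(res$n_pairs, 120)
  expect_lt(res$global_rmsd, 2)
  td <- tidy(res)
  expect_equal(td$domain, c("global", "core"))
  expect_true(all(td$rmsd >= 0))
  expect_equal(td$class[1], as.character(classify_rmsd(res$global_rmsd)))
})
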