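test_that("global alignment handles the hand-checked deletion case", {
  aln <- global_align("MKV", "MV")
  expect_equal(nchar(aln$pattern_aligned), 3)
  expect_equal(stringr::str_count(aln$subject_aligned, "-"), 1)
  # score by hand: M-M (5) + V-V (4) - (10 + 1 * 0.2)
  expect_equal(aln$score, 5 + 4 - 10.2, tolerance = 1e-5)
})

test_that("pairwise identity follows the gap-as-difference convention", {
  expect_equal(pairwise_identity(c(strrep("A", 100), strrep("A", 100))), 100)
  a <- paste0(strrep("A", 99), "C")
  b <- strrep("A", 100)
  expect_equal(pairwise_identity(c(a, b)), 99)
  # 90 matches, 5 mismatches, 5 gap columns -> 90/100
  a2 <- paste0(strrep("A", 90), strrep("C", 5), strrep("-", 5))
  b2 <- paste0(strrep("A", 90), strrep("D", 5), strrep("E", 5))
  expect_equal(pairwise_identity(c(a2, b2)), 90)
  expect_equal(pairwise_identity(c(a2, b2), ignore_gaps = TRUE),
               100 * 90 / 95)
  # dual-gap columns are excluded either way
  expect_equal(pairwise_identity(c("AB--", "AB--")), 100)
})

test_that("identity matrix is symmetric with unit diagonal and filters length", {
  set.seed(19)
  base <- random_protein(420)
  prots <- c(
    s1 = base,
    s2 = base,
    s3 = paste0(substr(base, 1, 400), random_protein(20)),
    short = substr(base, 1, 399)
  )
  im <- build_identity_matrix(prots, min_len = 400)
  expect_false("short" %in% im$labels)
  expect_true("s3" %in% im$labels)
  expect_equal(diag(im$values), setNames(rep(100, 3), im$labels))
  expect_lt(max(abs(im$values - t(im$values))), 1e-9)
  expect_equal(im$values["s1", "s2"], 100)
  expect_setequal(im$order, im$labels)
  expect_error(build_identity_matrix(prots[4], min_len = 400), "fewer than 2")
})

test_that("matrix values are input-order invariant", {
  set.seed(23)
  base <- random_protein(410)
  prots <- setNames(
    vapply(1:4, function(i) {
      unname(evolve_protein(base, "(x:0.15);", rate = 1))
    }, character(1)),
    paste0("p", 1:4)
  )
  im1 <- build_identity_matrix(prots)
  im2 <- build_identity_matrix(rev(prots))
  expect_equal(im1$values[im1$labels, im1$labels],
               im2$values[im1$labels, im1$labels])
})

test_that("identity decreases with tree distance in rank terms", {
  set.seed(29)
  root <- random_protein(450)
  tr <- ape::rcoal(10)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.4
  tips <- evolve_protein(root, tr, rate = 1)
  im <- build_identity_matrix(tips, min_len = 100)
  td <- ape::cophenetic.phylo(tr)[im$labels, im$labels]
  ut <- upper.tri(td)
  rc <- stats::cor(td[ut], im$values[ut], method = "spearman")
  expect_lt(rc, -0.9)
})

test_that("demarcation follows the ICTV thresholds and is monotone", {
  expect_equal(as.character(classify_pair(90, 85)$level), "same_species")
  expect_equal(as.character(classify_pair(86, 70)$level), "same_genus")
  expect_equal(as.character(classify_pair(30, 95)$level), "distinct")
  # boundaries are strict for species, inclusive for the genus floor
  expect_equal(as.character(classify_pair(85, 85)$level), "same_genus")
  expect_equal(as.character(classify_pair(90, 80)$level), "same_genus")
  expect_equal(as.character(classify_pair(35, 10)$level), "same_genus")
  expect_equal(as.character(classify_pair(34.999, 10)$level), "distinct")
  # raising identity never demotes the level
  lv <- classify_pair(seq(0, 100, by = 0.5), 90)$level
  expect_true(all(diff(as.integer(lv)) <= 0))
  expect_error(classify_pair(120, 50), "0, 100")
})

test_that("novel-taxon flagging uses the 75% ceiling", {
  m <- matrix(c(100, 60, 74, 60, 100, 80, 74, 80, 100), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  im <- structure(list(labels = c("x", "y", "z"), values = m,
                       order = c("x", "y", "z"), tree = NULL),
                  class = "identity_matrix")
  expect_true(flag_novel(im, "x")$novel)
  expect_false(flag_novel(im, "y")$novel)
  expect_equal(flag_novel(im, "x")$max_identity, 74)
  expect_error(flag_novel(im, "nope"), "not in matrix")
})

test_that("column trimming keeps consensus columns by hand count", {
  msa <- c(a = "MKVA-C",
           b = "MKVA-C",
           c = "MQWA-C",
           d = "MQY--C")
  # col1 M/M/M/M 100%; col2 K 50%; col3 V 50%; col4 A 100% (3 of 3 non-gap);
  # col5 all gaps -> dropped; col6 C 100%
  tr <- trim_columns(msa, min_consensus = 50)
  expect_equal(attr(tr, "kept"), c(1, 2, 3, 4, 6))
  expect_equal(unname(tr["a"]), "MKVAC")
  # a column of 4 distinct residues at 25% consensus is dropped
  msa2 <- c(a = "AM", b = "CM", c = "DM", d = "EM")
  expect_equal(attr(trim_columns(msa2, 50), "kept"), 2)
  expect_error(trim_columns(c(a = "AB", b = "ABC")), "rectangular")
})
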