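test_that("clock trees get unit rates and depth-proportional heights", {
  tt <- reltime_heights("((A:1,B:1):2,(C:2,D:2):1);")
  expect_true(all(abs(tt$rates$rate - 1) < 1e-12))
  # node heights: root 3, AB node 1, CD node 2 -> relative 1, 1/3, 2/3
  expect_equal(unname(tt$relative_heights[5:7]), c(1, 1 / 3, 2 / 3))
})

test_that("the two-rate hand example is corrected as derived by hand", {
  # ((A:1,B:3):1,C:4): root step gives lineage lengths 3 and 4, rates
  # 6/7 and 8/7; after dividing the AB subtree by 6/7 the AB node sees
  # stems 7/6 and 7/2, hence r_A = 0.5, r_B = 1.5; corrected tip paths are
  # all 3.5 and the AB node height is 7/3 -> relative 2/3
  tt <- reltime_heights("((A:1,B:3):1,C:4);")
  r <- tt$rates
  rate_of <- function(tip) {
    r$rate[r$child == match(tip, tt$tree$tip.label)]
  }
  expect_equal(rate_of("A"), (6 / 7) * 0.5)
  expect_equal(rate_of("B"), (6 / 7) * 1.5)
  expect_equal(rate_of("C"), 8 / 7)
  expect_equal(unname(tt$heights[4]), 3.5)
  expect_equal(unname(tt$relative_heights[5]), 2 / 3)
  # local rates at the AB node (stem rate factored out) are 0.5 and 1.5
  expect_equal(rate_of("A") / (6 / 7), 0.5)
  expect_equal(rate_of("B") / (6 / 7), 1.5)
})

test_that("relative heights are invariant to global branch scaling", {
  set.seed(4)
  tr <- ape::rtree(12)
  tt1 <- reltime_heights(tr)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 7.3
  tt2 <- reltime_heights(tr2)
  expect_equal(tt1$relative_heights, tt2$relative_heights, tolerance = 1e-12)
})

test_that("heights strictly decrease from root to tips", {
  set.seed(6)
  tr <- ape::rcoal(16)
  tt <- reltime_heights(tr)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
    if (tt$heights[p] > 0) {
      expect_gte(tt$heights[p], tt$heights[c])
    }
  }
})

test_that("calibration scales by least squares through the origin", {
  tt <- reltime_heights("((A:1,B:1):1,C:2);")
  # AB node at relative height 0.5 set to 11 MYA -> scale 22, root 22
  cal <- tibble::tibble(tip_a = "A", tip_b = "B", age_mya = 11,
                        kind = "point")
  ct <- calibrate_tree(tt, cal)
  expect_equal(ct$scale, 22)
  expect_equal(unname(ct$ages[4]), 22)
  # two consistent calibrations give the same scale
  tt2 <- reltime_heights("(((A:1,B:1):1,C:2):1,D:3);")
  cal2 <- tibble::tibble(tip_a = c("A", "A"), tip_b = c("B", "C"),
                         age_mya = c(10, 20), kind = "point")
  ct2 <- calibrate_tree(tt2, cal2)
  expect_equal(ct2$scale, 30)
  # three noisy calibrations: closed-form least squares oracle
  t_rel <- c(1 / 3, 2 / 3, 1)
  ages <- c(12, 19, 33)
  cal3 <- tibble::tibble(tip_a = c("A", "A", "A"),
                         tip_b = c("B", "C", "D"),
                         age_mya = ages, kind = "point")
  ct3 <- calibrate_tree(tt2, cal3)
  expect_equal(ct3$scale, sum(t_rel * ages) / sum(t_rel^2))
  # a violated maximum-age constraint is reported
  cal4 <- tibble::tibble(tip_a = c("A", "A"), tip_b = c("B", "D"),
                         age_mya = c(10, 5), kind = c("point", "max"))
  expect_warning(calibrate_tree(tt2, cal4), "violated")
})

test_that("outgroup nodes carry no ages but the ingroup root is timed", {
  tt <- reltime_heights("(((A:1,B:1):1,C:2):2,(O1:1,O2:1):3);")
  tt <- exclude_outgroup(tt, c("O1", "O2"))
  cal <- tibble::tibble(tip_a = "A", tip_b = "B", age_mya = 11,
                        kind = "point")
  ct <- calibrate_tree(tt, cal)
  td <- tidy(ct)
  out_nodes <- td$label %in% c("O1", "O2")
  expect_true(all(is.na(td$age_mya[out_nodes])))
  expect_true(all(!td$timed[out_nodes]))
  # ingroup mrca (of A, B, C) is timed; the root is not
  ing_mrca <- ape::getMRCA(ct$tree, c("A", "B", "C"))
  root <- length(ct$tree$tip.label) + 1
  expect_false(is.na(td$age_mya[td$node == ing_mrca]))
  expect_true(is.na(td$age_mya[td$node == root]))
  # calibrating on an outgroup-side node errors
  bad <- tibble::tibble(tip_a = "O1", tip_b = "O2", age_mya = 5,
                        kind = "point")
  expect_error(calibrate_tree(tt, bad), "untimed")
  # degenerate outgroups
  expect_error(exclude_outgroup(tt, c("A", "B", "C", "O1", "O2")),
               "all tips")
  expect_error(exclude_outgroup(tt, c("A", "O1")), "monophyletic")
  # single-tip outgroup: only that side is untimed
  tt1 <- exclude_outgroup(reltime_heights("((A:1,B:1):1,C:2);"), "C")
  expect_false(match("C", tt1$tree$tip.label) %in% tt1$timed_nodes)
})

test_that("clade-wise rate shifts are corrected to near-true node ages", {
  set.seed(15)
  errs <- replicate(20, {
    tr <- ape::rcoal(16)
    depths <- ape::node.depth.edgelength(tr)
    true_age <- max(depths) - depths          # ultrametric node ages
    shifted <- tr
    internal_edges <- which(shifted$edge[, 2] > length(tr$tip.label))
    e <- sample(internal_edges, 1)
    clade_root <- shifted$edge[e, 2]
    desc <- phangorn::Descendants(shifted, clade_root, "all")
    in_clade <- shifted$edge[, 2] %in% c(desc, clade_root)
    shifted$edge.length[in_clade] <- shifted$edge.length[in_clade] * 2
    tt <- reltime_heights(shifted)
    cal_node <- length(tr$tip.label) + 1      # calibrate on the root
    est <- tt$relative_heights * true_age[cal_node]
    idx <- (length(tr$tip.label) + 2):length(est)   # non-root internals
    ok <- true_age[idx] > 0.05 * max(true_age)
    median(abs(est[idx][ok] - true_age[idx][ok]) / true_age[idx][ok])
  })
  expect_lt(median(errs), 0.05)
})
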