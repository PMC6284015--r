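test_that("newick read/write round-trips topology and branch lengths", {
  tt <- read_tree("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tt$phy), 3L)
  expect_equal(root_age(tt), 2)
  ## round-trip a 100-tip random tree: all bipartitions preserved
  set.seed(2)
  phy <- ape::rtree(100)
  tt2 <- time_tree(phy)
  rt <- read_tree(write_tree(tt2))
  expect_identical(clades_of(rt$phy), clades_of(phy))
  expect_equal(sort(rt$phy$edge.length), sort(phy$edge.length),
               tolerance = 1e-8)
})

test_that("polytomies parse as unresolved and resolve uniformly", {
  star <- read_tree("(A,B,C);")
  expect_false(pangaea:::is_binary_rooted(star$phy))
  ## a trichotomy has 3 unordered resolutions, each with frequency 1/3
  set.seed(5)
  res <- replicate(3000, {
    r <- resolve_polytomies(star, seed = sample.int(1e8, 1))
    paste(clades_of(r$phy), collapse = ";")
  })
  tab <- table(res)
  expect_equal(length(tab), 3L)
  p <- 1 / 3
  se <- sqrt(p * (1 - p) / 3000)
  expect_true(all(abs(tab / 3000 - p) < 3 * se))
  ## binary input is returned unchanged
  bin <- read_tree("((A:1,B:1):1,C:2);")
  expect_identical(resolve_polytomies(bin, seed = 1), bin)
  ## 5-way polytomy becomes binary with 4 internal nodes
  r5 <- resolve_polytomies(read_tree("(A,B,C,D,E);"), seed = 3)
  expect_true(pangaea:::is_binary_rooted(r5$phy))
  expect_equal(r5$phy$Nnode, 4L)
})

test_that("tip ages are drawn uniformly within stratigraphic intervals", {
  phy <- ape::read.tree(text = "((A,B),C);")
  tt <- time_tree(phy,
                  tip_fad = c(A = 295, B = 290, C = 300),
                  tip_lad = c(A = 290, B = 290, C = 290))
  draws <- t(replicate(300, {
    d <- draw_tip_ages(tt, seed = sample.int(1e8, 1))
    d$age[1:3]
  }))
  expect_true(all(draws[, 1] >= 290 & draws[, 1] <= 295))
  ## zero-width interval gives the exact age
  expect_true(all(draws[, 2] == 290))
  ## uniform moments on [290, 300]
  set.seed(8)
  x <- replicate(10000, draw_tip_ages(tt)$age[3])
  expect_lt(abs(mean(x) - 295), 3 * sqrt(100 / 12 / 10000))
  expect_lt(abs(stats::var(x) - 100 / 12), 1)
  ## inverted interval is rejected
  expect_error(time_tree(phy, tip_fad = c(A = 280), tip_lad = c(A = 290)),
               "inverted")
})

test_that("minimum-age calibration respects min_branch and root_max", {
  cherry <- time_tree(ape::read.tree(text = "(A:1,B:1);"))
  cherry$age[1:2] <- c(300, 295)
  cal <- calibrate_node_ages(cherry, root_max = 400, min_branch = 0.1)
  expect_gte(root_age(cal), 300.1)
  ## ladder of accumulated offsets
  lad <- time_tree(ape::read.tree(text = "((((A:1,B:1):1,C:1):1,D:1):1,E:1);"))
  lad$age[1:5] <- 290
  cal2 <- calibrate_node_ages(lad, min_branch = 1)
  expect_gte(root_age(cal2), 294)
  expect_true(all(cal2$phy$edge.length >= 1 - 1e-9))
  ## infeasible root constraint errors
  expect_error(calibrate_node_ages(lad, root_max = 292, min_branch = 1),
               "infeasible")
})

test_that("post-window tips are dropped without disturbing retained ages", {
  phy <- ape::read.tree(text = "((A:10,B:10):5,C:15);")
  tt <- time_tree(phy, tip_fad = c(A = 280, B = 278, C = 240),
                  tip_lad = c(A = 275, B = 270, C = 235))
  tt$age[1:3] <- c(276, 272, 238)
  tt <- calibrate_node_ages(tt, min_branch = 0.5)
  kept <- drop_post_window_clades(tt, window_end = 252)
  expect_identical(sort(kept$phy$tip.label), c("A", "B"))
  ## retained node age unchanged (the A-B ancestor)
  old_ab <- tt$age[ape::getMRCA(tt$phy, c("A", "B"))]
  expect_equal(root_age(kept), old_ab)
  ## no post-window tips -> identity; brute-force filter agreement
  expect_identical(drop_post_window_clades(tt, window_end = 230), tt)
  expect_identical(sort(kept$phy$tip.label),
                   sort(names(which(tt$tip_fad >= 252))))
})

test_that("time slicing keeps tips whose ghost lineage crosses the slice", {
  ## tip aged 285 on a branch from 310: ghost lineage spans the slice
  phy <- ape::read.tree(text = "(A:25,B:30);")
  tt <- time_tree(phy, tip_fad = c(A = 286, B = 281),
                  tip_lad = c(A = 284, B = 279))
  tt$age[1:2] <- c(285, 280)
  tt$age[3] <- 310
  tt <- pangaea:::sync_edge_lengths(tt)
  expect_identical(sort(time_slice(tt, 300, 295)), c("A", "B"))
  ## tip whose branch starts at 288 is excluded from a (300, 295) slice
  phy2 <- ape::read.tree(text = "(A:3,B:30);")
  t2 <- time_tree(phy2, tip_fad = c(A = 286, B = 281),
                  tip_lad = c(A = 284, B = 279))
  t2$age[1:2] <- c(285, 280)
  t2$age[3] <- 288
  expect_warning(res <- time_slice(t2, 300, 295), "does not intersect")
  expect_length(res, 0L)
  ## oracle: brute-force interval-overlap scan
  set.seed(21)
  cfg <- sim_config(n_tips = 20, seed = 33)
  tr <- simulate_fossil_tree(cfg)
  for (slice in list(c(320, 310), c(300, 290), c(275, 262))) {
    got <- sort(time_slice(tr, slice[1], slice[2]))
    parent <- tr$phy$edge[match(seq_len(20), tr$phy$edge[, 2]), 1]
    manual <- tr$phy$tip.label[sapply(seq_len(20), function(i) {
      obs <- c(tr$tip_lad[tr$phy$tip.label[i]], tr$tip_fad[tr$phy$tip.label[i]])
      br <- c(tr$age[i], tr$age[parent[i]])
      (obs[2] >= slice[2] && obs[1] <= slice[1]) ||
        (br[2] >= slice[2] && br[1] <= slice[1])
    })]
    expect_identical(got, sort(manual))
  }
})

test_that("clade subtrees agree with a pairwise-LCA brute force", {
  set.seed(9)
  cfg <- sim_config(n_tips = 15, seed = 14)
  tr <- simulate_fossil_tree(cfg)
  tips <- sample(tr$phy$tip.label, 4)
  sub <- clade_subtree(tr, tips)
  ## brute-force MRCA: intersect ancestor paths of all pairs
  anc_path <- function(phy, v) {
    out <- v
    repeat {
      p <- phy$edge[match(v, phy$edge[, 2]), 1]
      if (is.na(p)) break
      out <- c(out, p)
      v <- p
    }
    out
  }
  paths <- lapply(match(tips, tr$phy$tip.label), anc_path, phy = tr$phy)
  common <- Reduce(intersect, paths)
  lca <- common[which.min(tr$age[common])]
  expect_equal(root_age(sub), tr$age[lca])
  expect_identical(sort(sub$phy$tip.label),
                   sort(tr$phy$tip.label[pangaea:::descendant_tips(tr$phy, lca)]))
  ## whole tree and single cherry limits
  expect_identical(sort(clade_subtree(tr, tr$phy$tip.label)$phy$tip.label),
                   sort(tr$phy$tip.label))
  expect_error(clade_subtree(tr, c("nope1", "nope2")), "nope1")
})

test_that("age monotonicity holds after calibration and pruning (sweep)", {
  for (seed in 1:5) {
    cfg <- sim_config(n_tips = 25, seed = seed)
    tr <- simulate_fossil_tree(cfg)
    tr2 <- draw_tip_ages(tr, seed = seed)
    tr2 <- calibrate_node_ages(tr2, root_max = 409.4)
    expect_silent(pangaea:::validate_time_tree(tr2))
    e <- tr2$phy$edge
    expect_true(all(tr2$age[e[, 1]] > tr2$age[e[, 2]]))
  }
})
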