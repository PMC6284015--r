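test_that("state space enumerates exactly the permitted ranges", {
  ## 3 fully connected areas, cap 2: C(3,1) + C(3,2) = 6
  expect_length(space_full(3, 2)$masks, 6L)
  ## chain A-B-C, cap 2: {A,C} excluded by connectivity -> 5
  sp <- space_chain3()
  expect_length(sp$masks, 5L)
  expect_false("A+C" %in% sp$labels)
  ## brute-force connectivity oracle over all subsets
  adj <- adj_chain3() != 0
  conn_brute <- function(idx) {
    if (length(idx) <= 1) return(TRUE)
    for (perm in 1:50) {
      reach <- idx[1]
      repeat {
        add <- idx[sapply(idx, function(a) any(adj[reach, a])) &
                     !(idx %in% reach)]
        if (length(add) == 0) break
        reach <- c(reach, add)
      }
      return(setequal(reach, idx))
    }
  }
  subsets <- unlist(lapply(1:2, function(k) combn(3, k, simplify = FALSE)),
                    recursive = FALSE)
  expected <- Filter(conn_brute, subsets)
  expect_equal(sort(sp$masks),
               sort(vapply(expected, pangaea:::areas_mask, integer(1))))
  ## single area
  expect_length(build_state_space("A", max_range_size = 1)$masks, 1L)
  expect_error(build_state_space(c("A", "B"), max_range_size = 0), "max_range_size")
  ## connectivity off restores the size-capped power set
  sp_off <- build_state_space(c("A", "B", "C"), adj_chain3(),
                              max_range_size = 2, connected_only = FALSE)
  expect_length(sp_off$masks, 6L)
})

test_that("anagenetic generator has the stated rates and zero row sums", {
  sp <- space_full(2, 2)
  m <- biogeo_model(0.02, 0.01)
  Q <- anagenetic_generator(sp, m)
  expect_equal(Q["A", "A+B"], 0.02)
  expect_equal(Q["A+B", "A"], 0.01)
  expect_equal(Q["A", "0"], 0.01)         # single-area decay to null
  expect_equal(unname(rowSums(Q)), rep(0, nrow(Q)))
  ## d = e = 0: zero matrix, identity transitions at any t
  Q0 <- anagenetic_generator(sp, biogeo_model(0, 0))
  expect_equal(Q0, Q0 * 0)
  P <- make_propagator(Q0)(7.3)
  expect_equal(unname(P), diag(nrow(Q0)))
  ## no transition ever targets a range outside the permitted space
  sp13 <- build_state_space(pangaea_fixture()$areas,
                            pangaea_fixture()$adjacency, max_range_size = 2)
  Q13 <- anagenetic_generator(sp13, biogeo_model(0.05, 0.02))
  expect_identical(colnames(Q13), c(sp13$labels, "0"))
  ## dispersal rate scales with the number of adjacent occupied areas
  spc <- space_full(3, 3)
  Qc <- anagenetic_generator(spc, biogeo_model(0.02, 0))
  expect_equal(Qc["A+C", "A+B+C"], 0.04)  # B adjacent to both A and C
})

test_that("transition probabilities match a trajectory simulation", {
  sp <- space_chain3()
  m <- biogeo_model(0.08, 0.04)
  Q <- anagenetic_generator(sp, m)
  P <- make_propagator(Q)(10)
  ## eigen route agrees with scaling-and-squaring
  expect_equal(P, as.matrix(Matrix::expm(Q * 10)), tolerance = 1e-9,
               ignore_attr = TRUE)
  set.seed(31)
  n <- 20000
  end <- replicate(n, {
    cur <- 1L
    t <- 10
    repeat {
      r <- -Q[cur, cur]
      if (r <= 0) break
      t <- t - stats::rexp(1, r)
      if (t <= 0) break
      cur <- sample(seq_len(nrow(Q))[-cur], 1, prob = Q[cur, -cur])
    }
    cur
  })
  freq <- tabulate(end, nbins = nrow(Q)) / n
  se <- sqrt(P[1, ] * (1 - P[1, ]) / n)
  expect_true(all(abs(freq - P[1, ]) <= 3 * pmax(se, 1e-4)))
})

test_that("cladogenesis tables implement the three rule sets", {
  sp <- space_full(3, 3)
  ab <- parse_range("A+B", sp$areas)
  ## DIVA-like {A,B}: the two ordered singleton splits, weight 1/2
  diva <- cladogenesis_table(sp, "DIVA-like")
  tab <- diva[[match(ab, sp$masks)]]
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$weight, c(0.5, 0.5))
  expect_setequal(tab$kind, "vicariance")
  ## every variant: single-area ancestor -> sympatric copy, weight 1
  for (v in c("DEC-like", "DIVA-like", "BAYAREA-like")) {
    t1 <- cladogenesis_table(sp, v)[[1]]
    expect_equal(nrow(t1), 1L)
    expect_identical(t1$kind, "sympatry")
    expect_equal(t1$left, t1$right)
  }
  ## BAYAREA-like: exact range copy at any size
  ba <- cladogenesis_table(sp, "BAYAREA-like")[[match(ab, sp$masks)]]
  expect_identical(ba$kind, "range copy")
  expect_equal(ba$left, ab)
  ## DEC-like size-3 fully connected: 6 subset-sympatry + 6 singleton
  ## vicariance events (brute enumeration of the rule set)
  abc <- parse_range("A+B+C", sp$areas)
  dec <- cladogenesis_table(sp, "DEC-like")[[match(abc, sp$masks)]]
  expect_equal(sum(dec$kind == "subset sympatry"), 6L)
  expect_equal(sum(dec$kind == "vicariance"), 6L)
  expect_equal(sum(dec$weight), 1)
  ## proper distributions everywhere; no single-area vicariance anywhere
  for (v in c("DEC-like", "DIVA-like", "BAYAREA-like")) {
    tabs <- cladogenesis_table(space_chain3(), v)
    for (i in seq_along(tabs)) {
      expect_equal(sum(tabs[[i]]$weight), 1)
      if (pangaea:::mask_size(space_chain3()$masks[i], 3) == 1L) {
        expect_false(any(tabs[[i]]$kind == "vicariance"))
      }
    }
  }
})

test_that("pruning likelihood equals brute-force enumeration", {
  set.seed(42)
  spaces <- list(space_chain3(), space_full(3, 2), space_full(2, 2))
  trees <- list(tree3(), tree4_ladder(), tree4_balanced())
  for (sp in spaces) {
    for (tr in trees) {
      labs <- tr$phy$tip.label
      tips <- as.list(stats::setNames(
        sample(sp$masks, length(labs), replace = TRUE), labs))
      for (v in c("DEC-like", "DIVA-like", "BAYAREA-like")) {
        m <- biogeo_model(0.05, 0.02, v)
        expect_equal(biogeo_loglik(tr, tips, m, sp),
                     enum_loglik(tr, tips, m, sp), tolerance = 1e-8)
      }
    }
  }
})

test_that("likelihood limits and invariances hold", {
  sp <- space_full(2, 2)
  m <- biogeo_model(0.05, 0.02)
  ## zero-length branches: likelihood 1 for matching tip states
  tr <- read_tree("(A:0,B:0);")
  tips <- list(A = sp$masks[1], B = sp$masks[1])
  ## both tips in {A}, zero branches: root must be {A} and split
  ## sympatrically; flat root prior contributes 1/K
  ll <- biogeo_loglik(tr, tips, m, sp)
  expect_equal(exp(ll), 1 / length(sp$masks))
  ## invariance to enumeration order (area relabelling)
  sp_rev <- build_state_space(c("B", "A"), max_range_size = 2)
  tr2 <- tree3()
  tips2 <- list(A = parse_range("A", sp$areas),
                B = parse_range("A+B", sp$areas),
                C = parse_range("B", sp$areas))
  tips2_rev <- list(A = parse_range("A", sp_rev$areas),
                    B = parse_range("A+B", sp_rev$areas),
                    C = parse_range("B", sp_rev$areas))
  expect_equal(biogeo_loglik(tr2, tips2, m, sp),
               biogeo_loglik(tr2, tips2_rev, m, sp_rev), tolerance = 1e-12)
  ## time-rescaling: doubling branch lengths and halving rates
  tr_fast <- tree3()
  tr_slow <- tree3()
  tr_slow$age <- tr_slow$age * 2
  tr_slow <- pangaea:::sync_edge_lengths(tr_slow)
  expect_equal(biogeo_loglik(tr_fast, tips2, biogeo_model(0.06, 0.04), sp),
               biogeo_loglik(tr_slow, tips2, biogeo_model(0.03, 0.02), sp),
               tolerance = 1e-10)
  ## unknown tip range errors name the taxon
  bad <- list(A = 999L, B = sp$masks[1], C = sp$masks[1])
  expect_error(biogeo_loglik(tr2, bad, m, sp), "A")
})

test_that("ancestral marginals equal joint enumeration and behave in limits", {
  sp <- space_chain3()
  tr <- tree3()
  tips <- list(A = parse_range("A", sp$areas),
               B = parse_range("A+B", sp$areas),
               C = parse_range("C", sp$areas))
  for (v in c("DEC-like", "DIVA-like")) {
    m <- biogeo_model(0.05, 0.02, v)
    marg <- ancestral_marginals(tr, tips, m, sp)
    em <- enum_marginals(tr, tips, m, sp)
    expect_equal(unname(marg), unname(em), tolerance = 1e-8)
    expect_equal(unname(rowSums(marg)), rep(1, nrow(marg)))
  }
  ## both daughters in {A} on short branches: root MAP is {A}
  short <- read_tree("(A:0.01,B:0.01);")
  tips_a <- list(A = parse_range("A", sp$areas), B = parse_range("A", sp$areas))
  marg2 <- ancestral_marginals(short, tips_a, biogeo_model(0.02, 0.01), sp)
  expect_identical(colnames(marg2)[which.max(marg2[1, ])], "A")
})

test_that("AIC selection follows the formula and reports ties", {
  mk_fit <- function(ll, variant) {
    structure(list(model = biogeo_model(0.01, 0.01, variant),
                   logLik = ll, convergence = 0L, k = 2L, n_tips = 10L),
              class = "biogeo_fit")
  }
  tab <- select_model(list(mk_fit(-10, "DIVA-like"), mk_fit(-12, "DEC-like")))
  expect_equal(tab$AIC[tab$variant == "DIVA-like"], 24)
  expect_identical(attr(tab, "best"), "DIVA-like")
  expect_false(attr(tab, "tie"))
  tie <- select_model(list(mk_fit(-10, "DIVA-like"), mk_fit(-10, "DEC-like")))
  expect_true(attr(tie, "tie"))
  ## fits on different data are refused
  bad <- mk_fit(-10, "DEC-like")
  bad$n_tips <- 99L
  expect_error(select_model(list(mk_fit(-10, "DIVA-like"), bad)),
               "different data")
})

test_that("fitted likelihood dominates probed grid points", {
  set.seed(77)
  cfg <- sim_config(n_tips = 30, seed = 19, max_range_size = 2)
  tr <- simulate_fossil_tree(cfg)
  sp <- space_chain3()
  sim <- simulate_tip_ranges(tr, biogeo_model(0.02, 0.01), sp, seed = 23)
  fit <- fit_ml(tr, sim$tip_ranges, "DIVA-like", sp)
  expect_equal(fit$convergence, 0L)
  for (g in list(c(0.005, 0.005), c(0.02, 0.01), c(0.1, 0.05))) {
    expect_gte(fit$logLik + 1e-6,
               biogeo_loglik(tr, sim$tip_ranges,
                             biogeo_model(g[1], g[2], "DIVA-like"), sp))
  }
})
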