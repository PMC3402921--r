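test_that("actions apply by exactly one pair and signal conflicts/clashes", {
  t <- toy()
  S <- apply_action(t$A, action("del", 1, 12))
  expect_equal(db_string(S), ".(((....))).....")
  expect_equal(pairs_of(apply_action(rna_structure(NULL, 16), action("add", 5, 16))),
               cbind(i = 5L, j = 16L), ignore_attr = TRUE)
  expect_error(apply_action(t$A, action("add", 5, 16)),
               class = "stackpath_clash")
  expect_error(apply_action(t$A, action("add", 1, 16)),
               class = "stackpath_conflict")
  expect_error(apply_action(t$A, action("del", 5, 16)),
               class = "stackpath_conflict")
})

test_that("chain validation walks the toy chain and pinpoints bad reorderings", {
  t <- toy()
  p <- simple_pathway(t$A, t$B, "outermost_first", "innermost_first")
  expect_equal(nrow(p), 8L)
  v <- validate_chain(t$A, t$B, p)
  expect_true(v$ok)
  expect_length(v$pts, 9L)
  # a1, a8, a2..a7: the first addition clashes right after the first deletion
  bad <- unclass(p)[c(1, 8, 2:7), ]
  vb <- validate_chain(t$A, t$B, bad)
  expect_false(vb$ok)
  expect_equal(vb$step, 2L)
  # empty action sequence with A = B
  v0 <- validate_chain(t$A, t$A, NULL)
  expect_true(v0$ok)
  expect_length(v0$pts, 1L)
  # right multiset, wrong end structure
  v2 <- validate_chain(t$A, t$A, unclass(p))
  expect_false(v2$ok)
})

test_that("simple pathways delete A-stacks then add B-stacks, stackwise", {
  t <- toy()
  p <- simple_pathway(t$A, t$B, "outermost_first", "innermost_first")
  expect_equal(unname(unclass(p)),
               cbind(c(rep(-1L, 4), rep(1L, 4)),
                     c(1:4, 8:5), c(12:9, 13:16)),
               ignore_attr = TRUE)
  expect_equal(nrow(simple_pathway(t$A, t$A)), 0L)
  one <- rna_structure(cbind(5:8, 16:13), 16)
  p2 <- simple_pathway(rna_structure(NULL, 16), one)
  expect_equal(nrow(p2), 4L)
  expect_true(all(unclass(p2)[, 1] == 1L))
  # multiset contract: exactly the symmetric difference
  for (dd in c("outermost_first", "innermost_first")) {
    for (fd in c("outermost_first", "innermost_first")) {
      q <- simple_pathway(t$A, t$B, dd, fd)
      expect_equal(nrow(q), bp_distance(t$A, t$B))
      expect_setequal(chain_multiset(q),
                      c(paste("-1", 1:4, 12:9), paste("1", 5:8, 16:13)))
      expect_true(validate_chain(t$A, t$B, q)$ok)
    }
  }
})

test_that("energy profile finds the saddle and the toy barrier", {
  t <- toy()
  m <- load_energy_backend("turner")
  pop <- initial_population(m, t$x, t$A, t$B)
  barriers <- vapply(pop, function(p) p$barrier, numeric(1))
  expect_equal(min(barriers), 12.10, tolerance = 0.001)
  best <- pop[[1]]
  expect_length(best$energies, 9L)
  expect_equal(best$energies[1], -6.60, tolerance = 0.011)
  expect_equal(best$energies[best$saddle_index + 1], 5.50, tolerance = 0.011)
  # empty chain
  p0 <- energy_profile(m, t$x, simple_pathway(t$A, t$A))
  expect_equal(p0$barrier, 0)
  expect_equal(p0$mean_excess, 0)
})

test_that("barrier dominates the endpoint energy difference", {
  set.seed(9)
  m <- load_energy_backend("simple")
  for (rep in 1:10) {
    inst <- random_instance(n = 20, k_stacks = 1, seed = 600 + rep)
    p <- simple_pathway(inst$A, inst$B)
    rec <- energy_profile(m, inst$sequence, p)
    eA <- evaluate_energy(m, inst$sequence, inst$A)
    eB <- evaluate_energy(m, inst$sequence, inst$B)
    expect_gte(rec$barrier + 1e-9, max(0, eB - eA))
    expect_equal(rec$mean_excess,
                 mean(rec$energies[-1] - rec$energies[1]))
  }
})

test_that("fitness order is barrier, then mean excess, then length", {
  mk <- function(barrier, me, m) {
    structure(list(barrier = barrier, mean_excess = me, m = m, seqno = 0),
              class = "pathway")
  }
  expect_equal(compare_fitness(mk(6.5, 1, 8), mk(7.25, 0, 8)), "p_better")
  expect_equal(compare_fitness(mk(5, 1.0, 8), mk(5, 2.0, 8)), "p_better")
  expect_equal(compare_fitness(mk(5, 1, 8), mk(5, 1, 10)), "p_better")
  expect_equal(compare_fitness(mk(5, 1, 8), mk(5, 1, 8)), "equal")
  # energies compared at print resolution
  expect_equal(compare_fitness(mk(5.001, 1, 8), mk(5.004, 1, 8)), "equal")
})
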