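toy_ctx <- function() {
  t <- toy()
  list(t = t, ctx = mutation_context(t$x, t$A, t$B),
       p = simple_pathway(t$A, t$B, "outermost_first", "innermost_first"))
}

test_that("feasible relocation intervals match the worked examples", {
  tc <- toy_ctx()
  # relocating a1 (del 1,12) after a4 keeps the chain valid
  iv1 <- feasible_interval(tc$t$A, tc$t$B, tc$p, 1)
  expect_true(4 %in% iv1)
  expect_true(validate_chain(tc$t$A, tc$t$B,
    stackpath:::reloc_rows(tc$p, 1, 4))$ok)
  # adjacent commuting move: relocating a3 after a2 is the identity
  expect_true(2 %in% feasible_interval(tc$t$A, tc$t$B, tc$p, 3))
  expect_equal(unname(unclass(stackpath:::reloc_rows(tc$p, 3, 2))),
               unname(unclass(tc$p)), ignore_attr = TRUE)
  # relocating a8 (add 5,16) to the front is infeasible
  expect_false(1 %in% feasible_interval(tc$t$A, tc$t$B, tc$p, 8))
  expect_false(validate_chain(tc$t$A, tc$t$B,
    stackpath:::reloc_rows(tc$p, 8, 1))$ok)
  # single-action chain has nothing to relocate
  one <- stackpath:::new_chain(
    cbind(1L, 5L, 16L), rna_structure(NULL, 16),
    rna_structure(cbind(5, 16), 16))
  expect_length(feasible_interval(attr(one, "A"), attr(one, "B"), one, 1),
                0L)
})

test_that("biased index choice has monotone weights of the stated shape", {
  expect_equal(biased_index_choice(4, 4, "front_loaded"), 4)
  set.seed(31)
  draws <- replicate(30000, biased_index_choice(1, 3, "front_loaded"))
  freq <- tabulate(draws, 3) / 30000
  # linear weights 3:2:1 normalized
  expect_equal(freq, c(3, 2, 1) / 6, tolerance = 0.02)
  draws_b <- replicate(30000, biased_index_choice(5, 7, "back_loaded", beta = 1))
  freq_b <- tabulate(draws_b - 4, 3) / 30000
  expect_equal(freq_b, c(1, 2, 3) / 6, tolerance = 0.02)
})

test_that("M1 relocates one action and preserves the multiset", {
  tc <- toy_ctx()
  set.seed(1)
  for (rep in 1:50) {
    q <- m1_move(tc$p, tc$ctx)
    expect_false(is.null(q))
    expect_true(validate_chain(tc$t$A, tc$t$B, q)$ok)
    expect_identical(chain_multiset(q), chain_multiset(tc$p))
  }
})

test_that("M2 swaps two actions; invalid draws are redrawn", {
  tc <- toy_ctx()
  set.seed(2)
  for (rep in 1:50) {
    q <- m2_swap(tc$p, tc$ctx)
    expect_false(is.null(q))
    expect_true(validate_chain(tc$t$A, tc$t$B, q)$ok)
    expect_identical(chain_multiset(q), chain_multiset(tc$p))
    ndiff <- sum(rowSums(unclass(q) != unclass(tc$p)) > 0)
    expect_true(ndiff %in% c(0L, 2L))  # 0 when the swapped pair commutes back
  }
  # the worked example: swapping a2 and a4 is valid
  sw <- unclass(tc$p)[c(1, 4, 3, 2, 5:8), ]
  expect_true(validate_chain(tc$t$A, tc$t$B, sw)$ok)
  # swapping a1 and a8 is not
  sw2 <- unclass(tc$p)[c(8, 2:7, 1), ]
  expect_false(validate_chain(tc$t$A, tc$t$B, sw2)$ok)
})

test_that("M3 inserts exactly one complementary action pair", {
  tc <- toy_ctx()
  set.seed(3)
  for (sign in c("add_then_del", "del_then_add")) {
    for (rep in 1:25) {
      q <- m3_insert_pair(tc$p, tc$ctx, sign)
      expect_false(is.null(q))
      expect_true(validate_chain(tc$t$A, tc$t$B, q)$ok)
      expect_equal(nrow(q), nrow(tc$p) + 2L)
      extra <- multiset_diff(chain_multiset(q), chain_multiset(tc$p))
      expect_length(extra, 2L)
      expect_length(unique(sub("^-?1 ", "", extra)), 1L)  # one pair, added and deleted
    }
  }
  # the temporary GU-stack construction: add(1,16) after a1, del before a8
  mat <- unclass(tc$p)
  with_gu <- rbind(mat[1, ], c(1L, 1L, 16L), mat[2:7, ], c(-1L, 1L, 16L),
                   mat[8, ])
  expect_true(validate_chain(tc$t$A, tc$t$B, with_gu)$ok)
})

test_that("M4 forms a compatible stack innermost-first after the anchor", {
  tc <- toy_ctx()
  set.seed(4)
  got_indirect <- FALSE
  for (rep in 1:40) {
    q <- m4_force_stack(tc$p, tc$ctx)
    expect_false(is.null(q))
    expect_true(validate_chain(tc$t$A, tc$t$B, q)$ok)
    # no action of p is lost
    expect_length(multiset_diff(chain_multiset(tc$p), chain_multiset(q)), 0L)
    if (nrow(q) > nrow(tc$p)) got_indirect <- TRUE
  }
  expect_true(got_indirect)
})

test_that("M4 skips stacks already contained in the structure", {
  # A = B = one helix; only stacks with a nonempty difference are usable
  x <- rna_seq("GGGGAAAACCCC")
  A <- parse_db("((((....))))")
  B <- parse_db("............")
  ctx <- mutation_context(x, A, B)
  p <- simple_pathway(A, B)
  set.seed(8)
  for (rep in 1:10) {
    q <- m4_force_stack(p, ctx)
    if (!is.null(q)) expect_true(validate_chain(A, B, q)$ok)
  }
})

test_that("M5 interleaves destruction and formation of incompatible stacks", {
  tc <- toy_ctx()
  set.seed(5)
  min_pairs_along <- function(chain) {
    v <- validate_chain(tc$t$A, tc$t$B, chain)
    min(vapply(v$pts, function(pt) sum(pt != 0L) / 2, numeric(1)))
  }
  interleaved <- FALSE
  for (rep in 1:40) {
    q <- m5_convert_stacks(tc$p, tc$ctx)
    expect_false(is.null(q))
    expect_true(validate_chain(tc$t$A, tc$t$B, q)$ok)
    expect_length(multiset_diff(chain_multiset(tc$p), chain_multiset(q)), 0L)
    if (min_pairs_along(q) > 0) interleaved <- TRUE
  }
  # the simple pathway melts to single-stranded; some M5 offspring avoid that
  expect_equal(min_pairs_along(tc$p), 0)
  expect_true(interleaved)
})

test_that("M5 returns nothing for chains without deletions", {
  x <- rna_seq("GGGGAAAACCCCUUUU")
  A <- rna_structure(NULL, 16)
  B <- parse_db("....((((....))))")
  ctx <- mutation_context(x, A, B)
  p <- simple_pathway(A, B)
  expect_null(m5_convert_stacks(p, ctx))
})

test_that("offspring streams are reproducible under a fixed seed", {
  tc <- toy_ctx()
  gen <- function() {
    set.seed(99)
    lapply(1:20, function(i) {
      q <- m1_move(tc$p, tc$ctx)
      unclass(m3_insert_pair(q, tc$ctx))
    })
  }
  expect_identical(gen(), gen())
})
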