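test_that("dot-bracket parsing recovers the expected pair sets", {
  A <- parse_db("((((....))))....")
  expect_equal(pairs_of(A),
               cbind(i = 1:4, j = c(12:9))[order(1:4), ],
               ignore_attr = TRUE)
  expect_equal(nrow(parse_db("................")), 0L)
  expect_error(parse_db("(..))"), "unbalanced")
  expect_error(parse_db("((..)"), "unbalanced")
  expect_error(parse_db("((x.))"), "illegal character")
})

test_that("rendering is the inverse of parsing", {
  B <- rna_structure(cbind(c(5, 6, 7, 8), c(16, 15, 14, 13)), 16)
  expect_equal(db_string(B), "....((((....))))")
  expect_equal(db_string(rna_structure(NULL, 4)), "....")
  expect_error(db_string(new_structure_bad <- structure(
    matrix(c(1L, 20L), ncol = 2), n = 16L, class = "rna_structure")),
    "outside")
})

test_that("parse/render round-trips on random structures", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(10:60, 1)
    # random valid structure: repeatedly add admissible random pairs
    pt <- integer(n)
    for (tries in 1:30) {
      ij <- sort(sample.int(n, 2))
      if (ij[2] - ij[1] < 4) next
      if (classify_pair_pt(pt, ij[1], ij[2]) == "ok") {
        pt[ij[1]] <- ij[2]; pt[ij[2]] <- ij[1]
      }
    }
    S <- structure_from_pt(pt)
    expect_identical(pairs_of(parse_db(db_string(S))), pairs_of(S))
  }
})

test_that("structure invariants are enforced", {
  expect_error(rna_structure(cbind(1, 1), 5), "i < j")
  expect_error(rna_structure(cbind(c(1, 1), c(8, 9)), 10), "more than once")
  expect_error(rna_structure(cbind(c(2, 5), c(11, 16)), 16), "pseudoknot")
  expect_error(rna_structure(cbind(1, 20), 16), "outside")
})

test_that("pairing rules admit canonical and wobble pairs with a minimum loop", {
  x <- rna_seq("GGGGAAAACCCCUUUU")
  expect_true(pair_allowed(x, 1, 16))    # G-U wobble
  expect_false(pair_allowed(x, 1, 2))    # too short and G-G
  expect_true(pair_allowed(x, 5, 16))    # A-U
  expect_false(pair_allowed(x, 5, 8))    # A-A
  expect_false(pair_allowed(x, 9, 13))   # C-U never pairs
  expect_false(pair_allowed(x, 4, 8))    # loop of 3 needed: j-i-1 = 3 ok...
  expect_true(pair_allowed(x, 4, 9))
})

test_that("sequence validation normalizes T and rejects other letters", {
  expect_warning(s <- rna_seq("GGAUT"), "normalized")
  expect_equal(unclass(s), "GGAUU", ignore_attr = TRUE)
  expect_error(rna_seq("GGAXU"), "invalid residue")
})

test_that("pair classification matches full re-validation from scratch", {
  expect_equal(classify_pair(rna_structure(cbind(1, 12), 16), 1, 16), "conflict")
  expect_equal(classify_pair(rna_structure(cbind(2, 11), 16), 5, 16), "clash")
  expect_equal(classify_pair(rna_structure(NULL, 16), 5, 16), "ok")
  # oracle: ok <=> adding the pair passes full structure validation
  set.seed(7)
  for (rep in 1:200) {
    n <- 20L
    pt <- integer(n)
    for (tries in 1:10) {
      ij <- sort(sample.int(n, 2))
      if (ij[2] - ij[1] >= 4 && classify_pair_pt(pt, ij[1], ij[2]) == "ok") {
        pt[ij[1]] <- ij[2]; pt[ij[2]] <- ij[1]
      }
    }
    S <- structure_from_pt(pt)
    ij <- sort(sample.int(n, 2))
    cls <- classify_pair(S, ij[1], ij[2])
    full_ok <- !inherits(try(
      rna_structure(rbind(pairs_of(S), ij), n), silent = TRUE), "try-error")
    expect_equal(cls == "ok", full_ok)
  }
})

test_that("base-pair distance is a metric and matches the toy value", {
  t <- toy()
  expect_equal(bp_distance(t$A, t$B), 8L)
  expect_equal(bp_distance(t$A, t$A), 0L)
  expect_equal(bp_distance(rna_structure(NULL, 16), t$A), 4L)
  set.seed(3)
  rand_S <- function(n) {
    pt <- integer(n)
    for (tries in 1:12) {
      ij <- sort(sample.int(n, 2))
      if (ij[2] - ij[1] >= 4 && classify_pair_pt(pt, ij[1], ij[2]) == "ok") {
        pt[ij[1]] <- ij[2]; pt[ij[2]] <- ij[1]
      }
    }
    structure_from_pt(pt)
  }
  for (rep in 1:30) {
    A <- rand_S(24); B <- rand_S(24); C <- rand_S(24)
    expect_equal(bp_distance(A, B), bp_distance(B, A))
    expect_true(bp_distance(A, C) <= bp_distance(A, B) + bp_distance(B, C))
    expect_identical(bp_distance(A, B) == 0L,
                     identical(pairs_of(A), pairs_of(B)))
  }
})

test_that("stack enumeration agrees with O(n^3) brute force", {
  x <- rna_seq("GGGGAAAACCCCUUUU")
  sta <- enumerate_stacks(x)
  sigs <- vapply(sta, stack_signature, character(1))
  expect_true(stack_signature(cbind(i = 1:4, j = 12:9)) %in% sigs)   # GC helix
  expect_true(stack_signature(cbind(i = 5:8, j = 16:13)) %in% sigs)  # AU helix
  expect_true(stack_signature(cbind(i = 1:4, j = 16:13)) %in% sigs)  # GU helix
  expect_equal(length(enumerate_stacks(rna_seq("AAAAAAAA"))), 0L)
  expect_equal(length(enumerate_stacks(x, min_stack_len = 16L)), 0L)
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(12:30, 1)
    xs <- rna_seq(paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
                               prob = c(.2, .3, .3, .2)), collapse = ""))
    got <- sort(vapply(enumerate_stacks(xs, 3L), stack_signature, character(1)))
    want <- sort(vapply(brute_stacks(xs, 3L), stack_signature, character(1)))
    expect_identical(got, want)
  }
})

test_that("stack compatibility follows the member-wise rule", {
  t <- toy()
  gc <- cbind(i = 1:4, j = 12:9)
  au <- cbind(i = 5:8, j = 16:13)
  expect_true(stack_compatible(gc, rna_structure(NULL, 16)))
  expect_false(stack_compatible(au, t$A))   # (5,16) crosses (4,9)
  expect_true(stack_compatible(gc, t$A))    # all members present
})
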