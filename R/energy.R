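#' Load a free-energy backend
#'
#' Two backends are provided. `"turner"` delegates evaluation to ViennaRNA's
#' `RNAeval` command-line program (nearest-neighbour Turner model); the
#' default parameter set is `"turner1999"` with `d1`-style dangling-end
#' treatment, matching the evaluation convention of the pathway-barrier
#' literature this package follows; `"turner2004"` selects ViennaRNA's
#' default parameters. `"simple"` is a built-in simplified nearest-neighbour
#' model (stacking table plus logarithmic loop penalties) that needs no
#' external program; it is a test vehicle and makes no claim to match
#' Turner values.
#'
#' @param name `"turner"` or `"simple"`.
#' @param parameter_set For the turner backend, `"turner1999"` (default) or
#'   `"turner2004"`; ignored by the simple backend.
#' @return An `energy_model` object.
#' @export
load_energy_backend <- function(name = c("simple", "turner"),
                                parameter_set = NULL) {
  name <- match.arg(name)
  m <- new.env(parent = emptyenv())
  m$name <- name
  m$cache <- new.env(parent = emptyenv())
  if (name == "turner") {
    m$parameter_set <- if (is.null(parameter_set)) "turner1999" else parameter_set
    if (!m$parameter_set %in% c("turner1999", "turner2004")) {
      stop("unknown parameter set '", m$parameter_set, "'")
    }
    m$dangle_mode <- "d1"
    bin <- Sys.which("RNAeval")
    if (!nzchar(bin)) {
      stop("turner backend requires ViennaRNA's RNAeval on the PATH; ",
           "install ViennaRNA or use the 'simple' backend")
    }
    m$rnaeval <- unname(bin)
    if (m$parameter_set == "turner1999") {
      par <- file.path(dirname(dirname(bin)), "share", "ViennaRNA",
                       "rna_turner1999.par")
      if (!file.exists(par)) {
        stop("Turner-1999 parameter file not found at ", par)
      }
      m$param_file <- par
    } else {
      m$param_file <- NULL   # ViennaRNA default (Turner 2004)
    }
  } else {
    m$parameter_set <- "simple"
    m$dangle_mode <- "none"
  }
  class(m) <- "energy_model"
  m
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Energy model: ", x$name, " (", x$parameter_set,
      if (x$name == "turner") ", d1 dangles", ")\n", sep = "")
  invisible(x)
}

#' Free energy of a secondary structure
#'
#' @param m An `energy_model` from [load_energy_backend()].
#' @param x An `rna_seq`.
#' @param S An `rna_structure` or a dot-bracket string.
#' @return Free energy in kcal/mol. The open (empty) structure has energy 0.
#' @export
evaluate_energy <- function(m, x, S) {
  db <- if (inherits(S, "rna_structure")) db_string(S) else S
  evaluate_many(m, x, db)[[1L]]
}

#' Free energies of several structures at once
#'
#' Vectorized form of [evaluate_energy()]; for the turner backend all
#' uncached structures are sent to `RNAeval` in a single call. Results are
#' memoized per model, keyed on sequence and structure, which is invisible
#' behaviourally (evaluation is a pure function of both).
#'
#' @inheritParams evaluate_energy
#' @param dbs Character vector of dot-bracket strings.
#' @return Numeric vector of energies (kcal/mol).
#' @export
evaluate_many <- function(m, x, dbs) {
  stopifnot(inherits(m, "energy_model"))
  xs <- unclass(x)
  if (any(nchar(dbs) != nchar(xs))) {
    stop("structure/sequence length mismatch")
  }
  keys <- paste0(xs, "|", dbs)
  out <- rep(NA_real_, length(dbs))
  for (k in seq_along(keys)) {
    v <- m$cache[[keys[k]]]
    if (!is.null(v)) out[k] <- v
  }
  todo <- which(is.na(out))
  if (length(todo)) {
    new <- if (m$name == "turner") {
      rnaeval_energies(m, xs, dbs[todo])
    } else {
      vapply(dbs[todo], function(db) simple_energy(x, parse_db(db)),
             numeric(1), USE.NAMES = FALSE)
    }
    for (k in seq_along(todo)) m$cache[[keys[todo[k]]]] <- new[k]
    out[todo] <- new
  }
  out
}

rnaeval_energies <- function(m, xs, dbs) {
  input <- paste0(xs, "\n", dbs, "\n", collapse = "")
  args <- c("-d1")
  if (!is.null(m$param_file)) args <- c(args, "-P", m$param_file)
  res <- suppressWarnings(
    system2(m$rnaeval, args, input = input, stdout = TRUE, stderr = TRUE)
  )
  hits <- regmatches(res, regexpr("\\(\\s*(-?[0-9]+\\.[0-9]+)\\)\\s*$", res))
  vals <- as.numeric(sub("[()\\s]*", "", gsub("[() ]", "", hits)))
  if (length(vals) != length(dbs) || anyNA(vals)) {
    stop("RNAeval returned ", length(vals), " energies for ", length(dbs),
         " structures; output was:\n", paste(res, collapse = "\n"))
  }
  vals
}

# ---- built-in simplified nearest-neighbour model ---------------------------
#
# Stacking free energies (kcal/mol) for pair-over-pair steps, loosely
# Turner-like, all negative; loop penalties are logarithmic in loop size and
# multiloops affine in branches/unpaired bases. Constants below are the whole
# parameterization.

simple_pair_types <- c("AU", "UA", "GC", "CG", "GU", "UG")

simple_stack_table <- local({
  M <- matrix(c(
    # inner:  AU    UA    GC    CG    GU    UG      outer
            -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,   # AU
            -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,   # UA
            -2.1, -2.2, -3.3, -2.4, -1.4, -2.1,   # GC
            -2.1, -2.4, -3.4, -3.3, -2.1, -2.5,   # CG
            -1.3, -1.4, -2.5, -2.1, -0.5, -1.3,   # GU
            -1.0, -0.6, -2.1, -1.4, -1.3, -0.5),  # UG
    nrow = 6, byrow = TRUE,
    dimnames = list(simple_pair_types, simple_pair_types))
  # strand-reversal symmetry: stack (p over q) == (rev q over rev p)
  rev_type <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")
  Msym <- M
  for (p in simple_pair_types) for (q in simple_pair_types) {
    Msym[p, q] <- (M[p, q] + M[rev_type[q], rev_type[p]]) / 2
  }
  Msym
})

simple_hairpin  <- function(L) 4.5 + 1.6 * log(L / 3)
simple_bulge    <- function(L) 3.6 + 1.2 * log(L)
simple_internal <- function(L) 2.6 + 1.1 * log(L / 2)
simple_multi    <- function(branches, unpaired) 3.4 + 0.4 * branches + 0.1 * unpaired

simple_energy <- function(x, S) {
  if (!nrow(S)) return(0)
  ch <- seq_chars(x)
  pt <- pair_table(S)
  e <- 0
  for (r in seq_len(nrow(S))) {
    i <- S[r, 1L]; j <- S[r, 2L]
    # children: maximal pairs directly enclosed by (i, j)
    kids <- matrix(integer(0), ncol = 2L)
    u <- 0L
    k <- i + 1L
    while (k < j) {
      if (pt[k] == 0L) {
        u <- u + 1L
        k <- k + 1L
      } else {
        kids <- rbind(kids, c(k, pt[k]))
        k <- pt[k] + 1L
      }
    }
    nk <- nrow(kids)
    if (nk == 0L) {
      e <- e + simple_hairpin(u)
    } else if (nk == 1L) {
      if (u == 0L) {
        outer <- paste0(ch[i], ch[j])
        inner <- paste0(ch[kids[1L, 1L]], ch[kids[1L, 2L]])
        e <- e + simple_stack_table[outer, inner]
      } else if (kids[1L, 1L] == i + 1L || kids[1L, 2L] == j - 1L) {
        e <- e + simple_bulge(u)
      } else {
        e <- e + simple_internal(u)
      }
    } else {
      e <- e + simple_multi(nk + 1L, u)
    }
  }
  e
}
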