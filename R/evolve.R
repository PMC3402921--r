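#' Control parameters for the evolutionary search
#'
#' Defaults follow the reference configuration of the stack-guided
#' evolutionary search: at most `MAX` base iterations (the search continues
#' past `MAX` only while it keeps improving), a plateau window of `gamma`
#' iterations, `L` expected offspring per parent per generation split over
#' the five mutation strategies, an elite of `l1` pathways carried into the
#' offspring list, at most `l2` offspring kept per parent, and a population
#' of at most `l3` pathways.
#'
#' @param MAX Iteration budget (default 10).
#' @param gamma Plateau window in iterations (default 5).
#' @param L Expected offspring per parent per generation (default 100).
#' @param L_min Offspring floor per strategy for poorly performing
#'   strategies (default 3).
#' @param l1 Elite count carried over each generation (default 10).
#' @param l2 Offspring kept per parent (default 5).
#' @param l3 Population size (default 100).
#' @param seed Integer seed for the random source; `NULL` leaves the RNG
#'   state untouched.
#' @param energy `"simple"` or `"turner"` energy backend.
#' @param parameter_set Turner parameter set (see [load_energy_backend()]).
#' @param min_stack_len,min_hairpin Structural knobs (defaults 4 and 3).
#' @param retry_limit Failed draws per offspring attempt (default 50).
#' @param beta Bias exponent for position choices (default 1).
#' @param literal_floor If `TRUE`, stopping condition (1) compares the
#'   barrier against `|E(B) - E(A)|` literally; the default uses
#'   `max(0, E(B) - E(A))`, which is a true lower bound.
#' @return A list of class `ea_control`.
#' @export
ea_control <- function(MAX = 10L, gamma = 5L, L = 100L, L_min = 3L,
                       l1 = 10L, l2 = 5L, l3 = 100L, seed = NULL,
                       energy = c("simple", "turner"), parameter_set = NULL,
                       min_stack_len = 4L, min_hairpin = 3L,
                       retry_limit = 50L, beta = 1, literal_floor = FALSE) {
  energy <- match.arg(energy)
  stopifnot(MAX >= 1L, gamma >= 1L, L >= 1L, L_min >= 1L,
            l1 >= 1L, l2 >= 1L, l3 >= 1L, l2 <= L)
  structure(list(MAX = as.integer(MAX), gamma = as.integer(gamma),
                 L = as.integer(L), L_min = as.integer(L_min),
                 l1 = as.integer(l1), l2 = as.integer(l2),
                 l3 = as.integer(l3), seed = seed, energy = energy,
                 parameter_set = parameter_set,
                 min_stack_len = as.integer(min_stack_len),
                 min_hairpin = as.integer(min_hairpin),
                 retry_limit = as.integer(retry_limit), beta = beta,
                 literal_floor = literal_floor),
            class = "ea_control")
}

#' Initial population of simple pathways
#'
#' The initial population holds the four simple stack-wise pathways from
#' `A` to `B` (each combination of degradation and formation direction),
#' evaluated and sorted by fitness. When `A = B` it holds the single empty
#' pathway.
#'
#' @param model An `energy_model`.
#' @param x An `rna_seq`.
#' @param A,B Endpoint `rna_structure`s.
#' @return A fitness-sorted list of `pathway` records.
#' @export
initial_population <- function(model, x, A, B) {
  if (bp_distance(A, B) == 0L) {
    return(list(energy_profile(model, x, new_chain(NULL, A, B), "init")))
  }
  dirs <- c("outermost_first", "innermost_first")
  pop <- list()
  for (dd in dirs) for (fd in dirs) {
    pop <- c(pop, list(energy_profile(
      model, x, simple_pathway(A, B, dd, fd), "init")))
  }
  sort_pathways(pop)
}

#' Adaptive per-strategy offspring allocation
#'
#' In the first generation every strategy receives `L / Y` offspring. In
#' later generations strategy `y` receives a share of `L` proportional to
#' its success ratio `b_y / l_y` of the previous generation (offspring
#' selected into the population over offspring allowed), floored at
#' `L_min`; when no strategy had any success the split is uniform again.
#' The allocations are not renormalized, so their sum may exceed `L`.
#'
#' @param stats `NULL` for the first generation, else a list with numeric
#'   vectors `b` (successful offspring per strategy) and `l_prev` (previous
#'   allocation).
#' @param cfg An `ea_control`.
#' @param Y Number of strategies (default 5).
#' @return Integer vector of `Y` allocations.
#' @export
allocate_offspring <- function(stats, cfg, Y = 5L) {
  uniform <- rep(as.integer(round(cfg$L / Y)), Y)
  if (is.null(stats)) return(uniform)
  ratio <- ifelse(stats$l_prev > 0, stats$b / stats$l_prev, 0)
  if (all(ratio == 0)) return(uniform)
  pmax(cfg$L_min, as.integer(round(ratio / sum(ratio) * cfg$L)))
}

#' One generation of the evolutionary search
#'
#' Each parent produces its allocated offspring through every mutation
#' strategy; the best `l2` offspring of each parent join the offspring
#' list, which also retains the best `l1` pathways of the previous
#' population (elitism). Duplicated chains are dropped. The next population
#' is the best `l3` of the offspring list, and per-strategy success counts
#' are taken over the offspring of this generation that made it into the
#' population.
#'
#' @param P Previous population (fitness-sorted list of `pathway`s).
#' @param ctx A `mutation_context`.
#' @param cfg An `ea_control`.
#' @param model An `energy_model`.
#' @param alloc Integer vector of per-strategy offspring counts.
#' @return A list with `P` (next population), `OPT` (best pathway of the
#'   offspring list), `b` (per-strategy success counts) and `n_offspring`.
#' @export
next_generation <- function(P, ctx, cfg, model, alloc) {
  strategies <- mutation_strategies()
  Y <- length(strategies)
  seq_start <- .seqno_env$k
  O <- P[seq_len(min(cfg$l1, length(P)))]       # elite
  n_off <- 0L
  # produce all offspring chains first, then evaluate the whole
  # generation's structures in one backend call (cache warm-up)
  chains <- vector("list", length(P))
  for (pi in seq_along(P)) {
    cl <- list()
    for (y in seq_len(Y)) {
      for (r in seq_len(alloc[y])) {
        q <- strategies[[y]](P[[pi]]$chain, ctx)
        if (!is.null(q)) {
          cl <- c(cl, list(list(chain = q, strategy = names(strategies)[y])))
        }
      }
    }
    chains[[pi]] <- cl
    n_off <- n_off + length(cl)
  }
  all_dbs <- unlist(lapply(chains, function(cl) {
    lapply(cl, function(e) {
      v <- validate_chain(ctx$A, ctx$B, e$chain)
      vapply(v$pts, pt_db, character(1))
    })
  }))
  if (length(all_dbs)) evaluate_many(model, ctx$x, unique(all_dbs))
  for (pi in seq_along(P)) {
    T_list <- lapply(chains[[pi]], function(e) {
      energy_profile(model, ctx$x, e$chain, e$strategy)
    })
    if (length(T_list)) {
      T_list <- sort_pathways(T_list)
      O <- c(O, T_list[seq_len(min(cfg$l2, length(T_list)))])
    }
  }
  O <- dedup_pathways(sort_pathways(O))
  P_next <- O[seq_len(min(cfg$l3, length(O)))]
  b <- integer(Y)
  names(b) <- names(strategies)
  for (rec in P_next) {
    if (rec$seqno > seq_start && rec$strategy %in% names(b)) {
      b[rec$strategy] <- b[rec$strategy] + 1L
    }
  }
  list(P = P_next, OPT = O[[1L]], b = b, n_offspring = n_off)
}

#' Run the evolutionary search for a low-barrier pathway
#'
#' Evolves a population of action chains from the four simple pathways,
#' applying the five mutation strategies with adaptive offspring
#' allocation and elitism, and selecting on (barrier, mean excess, length).
#' The search stops when the barrier reaches the energy floor
#' `max(0, E(B) - E(A))`, when no improvement has occurred over `gamma`
#' consecutive iterations, or when `MAX` iterations have passed and the
#' last iteration brought no improvement.
#'
#' @param x An `rna_seq` (or character string).
#' @param A,B Endpoint structures (`rna_structure` or dot-bracket strings).
#' @param cfg An [ea_control()].
#' @return A list with `best` (the best `pathway` found), `trace` (data
#'   frame of generation, barrier, offspring and per-strategy statistics),
#'   `generations`, `E_A`, `E_B`, and `population`.
#' @export
run_ea <- function(x, A, B, cfg = ea_control()) {
  if (!inherits(x, "rna_seq")) x <- rna_seq(x)
  if (!inherits(A, "rna_structure")) A <- parse_db(A)
  if (!inherits(B, "rna_structure")) B <- parse_db(B)
  n <- seq_len_of(x)
  if (attr(A, "n") != n || attr(B, "n") != n) {
    stop("sequence and structures must have equal length")
  }
  check_pairs_admissible(x, A, cfg$min_hairpin, "A")
  check_pairs_admissible(x, B, cfg$min_hairpin, "B")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  model <- load_energy_backend(cfg$energy, cfg$parameter_set)
  E_A <- evaluate_energy(model, x, A)
  E_B <- evaluate_energy(model, x, B)
  floor_E <- if (cfg$literal_floor) abs(E_B - E_A) else max(0, E_B - E_A)

  P <- initial_population(model, x, A, B)
  opt_hist <- list(P[[1L]])                     # OPT_0
  if (bp_distance(A, B) == 0L) {
    return(list(best = P[[1L]], generations = 0L, E_A = E_A, E_B = E_B,
                trace = data.frame(generation = integer(0),
                                   barrier = numeric(0)),
                population = P))
  }
  ctx <- mutation_context(x, A, B, cfg$min_stack_len, cfg$min_hairpin,
                          cfg$retry_limit, cfg$beta)
  Y <- 5L
  stats <- NULL
  trace <- NULL
  k <- 0L
  hard_cap <- max(10L * cfg$MAX, 200L)          # safety net
  repeat {
    k <- k + 1L
    alloc <- allocate_offspring(stats, cfg, Y)
    gen <- next_generation(P, ctx, cfg, model, alloc)
    P <- gen$P
    opt_hist[[k + 1L]] <- gen$OPT
    stats <- list(b = as.numeric(gen$b), l_prev = as.numeric(alloc))
    trace <- rbind(trace, data.frame(
      generation = k, barrier = gen$OPT$barrier,
      saddle = gen$OPT$energies[gen$OPT$saddle_index + 1L],
      chain_length = gen$OPT$m, n_offspring = gen$n_offspring,
      t(stats$l_prev), t(stats$b)))
    # "improvement" for the stopping rules means a lower barrier: the
    # full tie-break (mean excess) can keep improving indefinitely as
    # chains absorb stabilizing detours, which would defeat the plateau
    eq_opt <- function(a, b) round(a$barrier, 2) == round(b$barrier, 2)
    if (gen$OPT$barrier <= floor_E + 1e-6) break
    if (k > cfg$gamma && eq_opt(opt_hist[[k + 1L]], opt_hist[[k + 1L - cfg$gamma]])) break
    if (k >= cfg$MAX && eq_opt(opt_hist[[k + 1L]], opt_hist[[k]])) break
    if (k >= hard_cap) {
      warning("search stopped at hard iteration cap ", hard_cap)
      break
    }
  }
  names(trace)[6:15] <- c(paste0("l_M", 1:5), paste0("b_M", 1:5))
  list(best = opt_hist[[k + 1L]], trace = trace, generations = k,
       E_A = E_A, E_B = E_B, population = P)
}

check_pairs_admissible <- function(x, S, min_hairpin, label) {
  if (!nrow(S)) return(invisible())
  ok <- vapply(seq_len(nrow(S)), function(r) {
    pair_allowed(x, S[r, 1L], S[r, 2L], min_hairpin)
  }, logical(1))
  if (!all(ok)) {
    warning("structure ", label, " contains ", sum(!ok),
            " pair(s) outside the canonical/wobble rules")
  }
  invisible()
}
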