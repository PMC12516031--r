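#' @useDynLib hcmdce, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif qlogis plogis qnorm pnorm optim nlminb sd var aggregate
#' @importFrom utils read.csv write.csv head
NULL

new_choice_design <- function(sets, attrs, priors, asc_prior, d_error = NA_real_,
                              seed = NA_integer_, trace = NULL) {
  structure(list(sets = sets, attrs = attrs, priors = priors,
                 asc_prior = asc_prior, d_error = d_error, seed = seed,
                 trace = trace),
            class = "choice_design")
}

#' @export
print.choice_design <- function(x, ...) {
  exp_sets <- unique(x$sets$set_id[!x$sets$is_qc])
  cat("Choice design: ", length(exp_sets), " experimental sets in ",
      length(unique(x$sets$block_id[!x$sets$is_qc])), " blocks, ",
      sum(x$sets$is_qc) / 2, " QC set(s)\n", sep = "")
  if (is.finite(x$d_error)) cat("D-error:", format(x$d_error, digits = 6), "\n")
  invisible(x)
}

# Zero-prior default on the coded scale; one entry per coded column.
zero_priors <- function(attrs) {
  p <- numeric(length(coded_names(attrs)))
  names(p) <- coded_names(attrs)
  p
}

# 3 x (K+1) coded matrix of one choice set: two insurance alternatives plus
# the opt-out (all attributes zero, ASC column one).
set_matrix <- function(coded_pair, K) {
  rbind(cbind(coded_pair, c(0, 0)), c(numeric(K), 1))
}

set_information <- function(coded_pair, beta, K) {
  Xs <- set_matrix(coded_pair, K)
  u <- drop(Xs %*% beta)
  p <- exp(u - max(u)); p <- p / sum(p)
  crossprod(Xs * sqrt(p)) - tcrossprod(crossprod(Xs, p))
}

derror_from_info <- function(info) {
  K <- nrow(info)
  d <- determinant(info, logarithm = TRUE)
  if (d$sign <= 0) return(Inf)
  ld <- as.numeric(d$modulus)
  if (!is.finite(ld) || ld < -200) return(Inf)
  exp(-ld / K)
}

#' D-error of a blocked choice design
#'
#' Computes `det(I(beta))^(-1/K)` where `I` is the multinomial-logit
#' information matrix accumulated over the experimental (non-QC) choice sets
#' and `K` is the number of utility parameters (the coded attribute
#' coefficients plus the opt-out alternative-specific constant). Each set
#' contributes three alternatives: the two insurance profiles and an opt-out
#' whose utility equals the ASC prior. Smaller values indicate a more
#' efficient design; the value is invariant to the ordering of sets.
#'
#' @param design A `choice_design`.
#' @param priors Named numeric vector of prior coefficients on the coded
#'   scale (defaults to the design's stored priors, else zeros).
#' @param asc_prior Prior for the opt-out constant (default the design's).
#' @return Positive scalar D-error.
#' @export
d_error <- function(design, priors = NULL, asc_prior = NULL) {
  attrs <- design$attrs
  if (is.null(priors)) priors <- design$priors
  if (is.null(priors)) priors <- zero_priors(attrs)
  if (is.null(asc_prior)) asc_prior <- design$asc_prior
  if (is.null(asc_prior)) asc_prior <- 0
  cn <- coded_names(attrs)
  if (length(priors) != length(cn)) {
    stop("priors must have one entry per coded column (", length(cn), ")")
  }
  sets <- design$sets[!design$sets$is_qc, , drop = FALSE]
  coded <- code_profiles(sets, attrs)
  K <- length(cn)
  beta <- c(priors, asc_prior)
  info <- matrix(0, K + 1, K + 1)
  for (sid in unique(sets$set_id)) {
    rows <- which(sets$set_id == sid)
    if (length(rows) != 2) stop("set ", sid, " does not have exactly 2 alternatives")
    info <- info + set_information(coded[rows, , drop = FALSE], beta, K)
  }
  out <- derror_from_info(info)
  if (!is.finite(out)) stop("design not identified: singular information matrix")
  out
}

#' Quality-control (dominance) choice set
#'
#' Constructs the attentiveness-screening task: one clearly most favorable
#' profile (best level of every attribute under the hypothesized signs) paired
#' with one clearly least favorable profile (worst levels). The dominated
#' profile is always alternative 2. QC sets are flagged and excluded from
#' D-error computation and from the estimation likelihood.
#'
#' @param attrs An `attribute_dictionary`.
#' @param set_id Identifier given to the set (default 0; reassigned when the
#'   set is appended to a design).
#' @return Two-row data frame (alternatives 1 and 2) with `is_qc = TRUE`.
#' @export
make_qc_set <- function(attrs, set_id = 0L) {
  best <- best_profile(attrs)
  worst <- worst_profile(attrs)
  stopifnot(is_dominated(worst, best, attrs))
  out <- rbind(best, worst)
  data.frame(set_id = set_id, block_id = NA_integer_, alt_id = 1:2,
             is_qc = TRUE, out, stringsAsFactors = FALSE)
}

# level index state helpers -------------------------------------------------

# lvl: n_sets x 2 x n_attr integer array of level indices
lvl_to_profiles <- function(lvl, attrs) {
  n_sets <- dim(lvl)[1]
  anames <- names(attrs$attributes)
  cols <- lapply(seq_along(anames), function(j) {
    levels_j <- attrs$attributes[[j]]$levels
    levels_j[as.vector(t(lvl[, , j]))]  # set-major, alt within set
  })
  names(cols) <- anames
  data.frame(set_id = rep(seq_len(n_sets), each = 2),
             alt_id = rep(1:2, n_sets),
             as.data.frame(cols, stringsAsFactors = FALSE),
             stringsAsFactors = FALSE)
}

profile_row <- function(lvl, s, a, attrs) {
  anames <- names(attrs$attributes)
  out <- lapply(seq_along(anames), function(j) attrs$attributes[[j]]$levels[lvl[s, a, j]])
  names(out) <- anames
  as.data.frame(out, stringsAsFactors = FALSE)
}

pair_ok <- function(lvl, s, attrs, screen = TRUE) {
  p1 <- profile_row(lvl, s, 1, attrs)
  p2 <- profile_row(lvl, s, 2, attrs)
  if (all(mapply(identical, as.list(p1), as.list(p2)))) return(FALSE)
  if (!screen) return(TRUE)
  !is_dominated(p1, p2, attrs) && !is_dominated(p2, p1, attrs)
}

# coded row of one profile from level indices, via precomputed per-attribute
# coding tables
coded_row <- function(lvl_vec, codetabs) {
  unlist(lapply(seq_along(codetabs), function(j) codetabs[[j]][lvl_vec[j], ]),
         use.names = FALSE)
}

make_codetabs <- function(attrs) {
  lapply(names(attrs$attributes), function(nm) {
    a <- attrs$attributes[[nm]]
    df <- data.frame(x = a$levels); names(df) <- nm
    code_profiles(df, attribute_dictionary(stats::setNames(list(a), nm)))
  })
}

#' Generate a D-efficient blocked choice design by coordinate exchange
#'
#' Random starting designs are improved by sweeping over every set,
#' alternative and attribute, trying each alternative level and accepting
#' strict D-error improvements, until a full sweep yields no improvement.
#' Candidate moves that would make the two profiles of a set identical,
#' leave one strictly dominated, or break near level balance (each level's
#' occurrence count within one unit of perfect balance, and present in at
#' least `n_blocks` distinct sets) are rejected; dominated pairs in the
#' random start are repaired by re-randomizing one attribute. The best design
#' over `n_restarts` restarts is blocked greedily (minimizing squared
#' deviation from perfect level balance per block, ties to the lowest block),
#' block-level coverage is repaired by pairwise swaps, and the dominance QC
#' set is appended. Deterministic given `seed`.
#'
#' @param attrs An `attribute_dictionary`.
#' @param n_sets Number of experimental sets (default 24).
#' @param n_blocks Number of blocks (default 4); must divide `n_sets`.
#' @param priors Named prior coefficient vector on the coded scale
#'   (default zeros, a utility-neutral design).
#' @param asc_prior Opt-out constant prior (default 0).
#' @param seed Integer seed (default 20230901).
#' @param n_restarts Number of random restarts (default 20).
#' @param max_sweeps Safety cap on exchange sweeps per restart.
#' @param screen_dominated Reject dominated pairs during the exchange
#'   (default `TRUE`). Turning the screen off admits classical
#'   utility-neutral benchmarks (e.g. orthogonal toy designs) in which every
#'   trade-off-free pairing would otherwise be excluded.
#' @return A `choice_design`; its `trace` element records the monotone
#'   D-error path of the winning restart and `initial_d_error` the D-error of
#'   that restart's random start.
#' @export
generate_design <- function(attrs, n_sets = 24L, n_blocks = 4L, priors = NULL,
                            asc_prior = 0, seed = 20230901L, n_restarts = 20L,
                            max_sweeps = 50L, screen_dominated = TRUE) {
  if (n_sets %% n_blocks != 0) stop("n_sets must be divisible by n_blocks")
  if (is.null(priors)) priors <- zero_priors(attrs)
  anames <- names(attrs$attributes)
  n_attr <- length(anames)
  nlev <- vapply(attrs$attributes, function(a) length(a$levels), integer(1))
  per_block_slots <- 2L * n_sets / n_blocks
  if (any(nlev > per_block_slots)) {
    stop("infeasible level coverage: block size ", per_block_slots,
         " profiles cannot cover attribute '", anames[which.max(nlev)],
         "' with ", max(nlev), " levels")
  }
  codetabs <- make_codetabs(attrs)
  K <- length(coded_names(attrs))
  beta <- c(priors, asc_prior)

  set_info_lvl <- function(lvl, s) {
    cp <- rbind(coded_row(lvl[s, 1, ], codetabs), coded_row(lvl[s, 2, ], codetabs))
    set_information(cp, beta, K)
  }

  # Near level balance is enforced throughout the exchange: each level's
  # occurrence count stays within +/-1 of perfect balance over the
  # 2 * n_sets profile slots, and each level touches at least n_blocks
  # distinct sets. The unconstrained utility-neutral optimum concentrates
  # linear attributes on extreme levels, which leaves middle levels too
  # scarce for any block assignment to cover them.
  slots <- 2L * n_sets
  lo <- pmax(floor(slots / nlev) - 1L, 1L)
  hi <- ceiling(slots / nlev) + 1L
  level_count <- function(lvl, j, lev) sum(lvl[, , j] == lev)
  distinct_sets <- function(lvl, j, lev) {
    sum(lvl[, 1L, j] == lev | lvl[, 2L, j] == lev)
  }
  level_ok <- function(lvl, j, lev) {
    level_count(lvl, j, lev) >= lo[j] && distinct_sets(lvl, j, lev) >= n_blocks
  }
  coverage_ok <- function(lvl) {
    for (j in seq_len(n_attr)) for (lev in seq_len(nlev[j])) {
      if (!level_ok(lvl, j, lev)) return(FALSE)
    }
    TRUE
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    rs <- local_rng(seed + r - 1L)
    lvl <- array(0L, dim = c(n_sets, 2L, n_attr))
    for (s in seq_len(n_sets)) {
      repeat {
        for (j in seq_len(n_attr)) lvl[s, , j] <- rs$sample_int(nlev[j], 2L)
        if (pair_ok(lvl, s, attrs, screen_dominated)) break
        # repair: re-randomize one attribute of alternative 2
        j <- rs$sample_int(n_attr, 1L)
        lvl[s, 2L, j] <- rs$sample_int(nlev[j], 1L)
        if (pair_ok(lvl, s, attrs, screen_dominated)) break
      }
    }
    # seed-level repair: inject under-represented levels until the balance
    # and distinct-set floors hold
    for (tries in seq_len(2000L)) {
      if (coverage_ok(lvl)) break
      fixed <- FALSE
      for (j in seq_len(n_attr)) for (lev in seq_len(nlev[j])) {
        if (level_ok(lvl, j, lev)) next
        cand_sets <- which(lvl[, 1L, j] != lev & lvl[, 2L, j] != lev)
        cand_sets <- cand_sets[order(rs$runif(length(cand_sets)))]
        for (s in cand_sets) {
          for (a in 1:2) {
            old <- lvl[s, a, j]
            if (level_count(lvl, j, old) - 1L < lo[j] ||
                distinct_sets(lvl, j, old) - 1L < n_blocks) next
            lvl[s, a, j] <- lev
            if (pair_ok(lvl, s, attrs, screen_dominated)) { fixed <- TRUE; break }
            lvl[s, a, j] <- old
          }
          if (fixed) break
        }
        if (fixed) break
      }
      if (!fixed) break
    }
    if (!coverage_ok(lvl)) {
      stop("infeasible level-coverage constraint in block 1 (cannot seat ",
           "every attribute level in ", n_blocks, " blocks)")
    }
    infos <- lapply(seq_len(n_sets), function(s) set_info_lvl(lvl, s))
    info <- Reduce(`+`, infos)
    cur <- derror_from_info(info)
    init_d <- cur
    trace <- cur
    sweep <- 0L
    repeat {
      sweep <- sweep + 1L
      improved <- FALSE
      for (s in seq_len(n_sets)) for (a in 1:2) for (j in seq_len(n_attr)) {
        old_lev <- lvl[s, a, j]
        best_lev <- old_lev
        best_d <- cur
        best_info_s <- NULL
        for (lev in seq_len(nlev[j])[-old_lev]) {
          lvl[s, a, j] <- lev
          if (level_count(lvl, j, old_lev) < lo[j] ||
              level_count(lvl, j, lev) > hi[j] ||
              distinct_sets(lvl, j, old_lev) < n_blocks ||
              !pair_ok(lvl, s, attrs, screen_dominated)) next
          new_info_s <- set_info_lvl(lvl, s)
          cand <- derror_from_info(info - infos[[s]] + new_info_s)
          if (is.finite(cand) && cand < best_d - 1e-12) {
            best_d <- cand; best_lev <- lev; best_info_s <- new_info_s
          }
        }
        lvl[s, a, j] <- best_lev
        if (best_lev != old_lev) {
          info <- info - infos[[s]] + best_info_s
          infos[[s]] <- best_info_s
          cur <- best_d
          trace <- c(trace, cur)
          improved <- TRUE
        }
      }
      if (!improved || sweep >= max_sweeps) break
    }
    if (is.null(best) || cur < best$d) {
      best <- list(lvl = lvl, d = cur, init_d = init_d, trace = trace)
    }
  }

  if (!is.finite(best$d)) {
    stop("design not identified: no feasible design with finite D-error found")
  }
  profiles <- lvl_to_profiles(best$lvl, attrs)
  blocks <- assign_blocks(best$lvl, attrs, n_blocks)
  profiles$block_id <- blocks[profiles$set_id]
  # renumber sets so that block 1 holds sets 1..n_sets/n_blocks, etc.
  ord <- order(profiles$block_id, profiles$set_id, profiles$alt_id)
  profiles <- profiles[ord, , drop = FALSE]
  profiles$set_id <- rep(seq_len(n_sets), each = 2)
  profiles$is_qc <- FALSE
  qc <- make_qc_set(attrs, set_id = n_sets + 1L)
  sets <- rbind(profiles[c("set_id", "block_id", "alt_id", "is_qc", anames)],
                qc[c("set_id", "block_id", "alt_id", "is_qc", anames)])
  rownames(sets) <- NULL
  out <- new_choice_design(sets, attrs, priors, asc_prior, d_error = best$d,
                           seed = seed,
                           trace = list(d_error = best$trace,
                                        initial_d_error = best$init_d))
  stopifnot(abs(d_error(out) - best$d) < 1e-8 * best$d)
  out
}

# Greedy balanced blocking with coverage repair. Multi-start over permuted
# greedy orders (deterministic) because the pairwise-swap repair can stall in
# a local optimum. Returns block id per set.
assign_blocks <- function(lvl, attrs, n_blocks, n_attempts = 25L) {
  n_sets <- dim(lvl)[1]
  n_attr <- dim(lvl)[3]
  nlev <- vapply(attrs$attributes, function(a) length(a$levels), integer(1))
  cap <- n_sets / n_blocks
  # per-set level count tables, flattened over (attr, level)
  keys <- unlist(lapply(seq_len(n_attr), function(j) paste0(j, ".", seq_len(nlev[j]))))
  set_counts <- t(vapply(seq_len(n_sets), function(s) {
    k <- paste0(rep(seq_len(n_attr), times = 2), ".", as.vector(t(lvl[s, , ])))
    tab <- table(factor(k, levels = keys))
    as.numeric(tab)
  }, numeric(length(keys))))
  target <- colSums(set_counts) / n_blocks
  penalty <- function(bc) 1e6 * sum(bc == 0) + sum(sweep(bc, 2, target)^2)

  attempt <- function(order) {
    block_of <- integer(n_sets)
    bcount <- matrix(0, n_blocks, length(keys))
    bsize <- integer(n_blocks)
    for (s in order) {
      open <- which(bsize < cap)
      dev <- vapply(open, function(b) {
        sum((bcount[b, ] + set_counts[s, ] - target)^2)
      }, numeric(1))
      b <- open[which.min(dev)]  # which.min breaks ties by lowest index
      block_of[s] <- b
      bcount[b, ] <- bcount[b, ] + set_counts[s, ]
      bsize[b] <- bsize[b] + 1L
    }
    # coverage repair: pairwise-swap local search on a penalized objective
    # (coverage holes dominate balance)
    cur <- penalty(bcount)
    repeat {
      if (sum(bcount == 0) == 0) break
      best_gain <- 0
      best_swap <- NULL
      for (s1 in seq_len(n_sets - 1L)) for (s2 in (s1 + 1L):n_sets) {
        b1 <- block_of[s1]; b2 <- block_of[s2]
        if (b1 == b2) next
        nb <- bcount
        nb[b1, ] <- nb[b1, ] - set_counts[s1, ] + set_counts[s2, ]
        nb[b2, ] <- nb[b2, ] - set_counts[s2, ] + set_counts[s1, ]
        gain <- cur - penalty(nb)
        if (gain > best_gain + 1e-9) {
          best_gain <- gain
          best_swap <- list(s1 = s1, s2 = s2, nb = nb)
        }
      }
      if (is.null(best_swap)) return(NULL)  # stalled with a hole left
      bcount <- best_swap$nb
      block_of[c(best_swap$s1, best_swap$s2)] <-
        c(block_of[best_swap$s2], block_of[best_swap$s1])
      cur <- penalty(bcount)
    }
    block_of
  }

  res <- attempt(seq_len(n_sets))
  k <- 0L
  while (is.null(res) && k < n_attempts) {
    k <- k + 1L
    rs <- local_rng(973L + k)
    res <- attempt(rs$sample(seq_len(n_sets), n_sets))
  }
  if (is.null(res)) {
    stop("infeasible level-coverage constraint in block 1")
  }
  res
}

#' Check that every block covers every attribute level
#'
#' @param design A `choice_design`.
#' @return Logical; `TRUE` iff each experimental block contains every level of
#'   every attribute at least once.
#' @export
block_coverage_ok <- function(design) {
  sets <- design$sets[!design$sets$is_qc, , drop = FALSE]
  for (b in unique(sets$block_id)) {
    blk <- sets[sets$block_id == b, , drop = FALSE]
    for (nm in names(design$attrs$attributes)) {
      lev <- design$attrs$attributes[[nm]]$levels
      if (!all(as.character(lev) %in% as.character(blk[[nm]]))) return(FALSE)
    }
  }
  TRUE
}

#' Write / read a choice design as CSV
#'
#' One row per set x alternative with columns `set_id`, `block_id`, `alt_id`,
#' `is_qc` and one column per attribute (raw levels).
#'
#' @param design A `choice_design`.
#' @param path File path.
#' @export
write_design <- function(design, path) {
  write.csv(design$sets, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param attrs Attribute dictionary used to re-validate the file.
#' @export
read_design <- function(path, attrs = huimin_attributes()) {
  sets <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_id", "block_id", "alt_id", "is_qc", names(attrs$attributes))
  if (!all(need %in% names(sets))) {
    stop("design file lacks columns: ", paste(setdiff(need, names(sets)), collapse = ", "))
  }
  sets$is_qc <- as.logical(sets$is_qc)
  new_choice_design(sets[need], attrs, priors = zero_priors(attrs), asc_prior = 0)
}

# Small deterministic RNG wrapper that does not disturb the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample_int = function(n, k) with_state(function() sample.int(n, k, replace = TRUE)),
    runif = function(n) with_state(function() runif(n)),
    rnorm = function(n) with_state(function() rnorm(n)),
    sample = function(x, k) with_state(function() sample(x, k))
  )
}
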