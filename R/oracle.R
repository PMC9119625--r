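# Run code under a temporary RNG seed (restoring the caller's RNG state),
# or under the current RNG stream when seed is NULL.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# One synchronous generation of the multi-type branching process, vectorized
# across roots. s_p/s_m/s_c are per-root counts of free plus/minus/binding
# sites in the current generation; returns per-root counts of children
# entered via each site. Binomial thinning implements the per-site
# multinomial (bond type or no bond).
.offspring <- function(s_p, s_m, s_c, th) {
  n <- length(s_p)
  cond <- function(p_rest, p_this) {
    if (p_rest > 0) min(1, p_this / p_rest) else 0
  }
  # free plus sites bond p->m with theta_pm: child entered via m
  k_pm <- rbinom(n, s_p, th$theta_pm)
  # free minus sites: p-ward (theta_mp) or brancher mother (theta_mc)
  k_mp <- rbinom(n, s_m, th$theta_mp)
  k_mc <- rbinom(n, s_m - k_mp, cond(1 - th$theta_mp, th$theta_mc))
  # free binding sites: linker crosslink, motor crosslink, or branch daughter
  k_ccL <- rbinom(n, s_c, th$theta_ccL)
  k_ccM <- rbinom(n, s_c - k_ccL, cond(1 - th$theta_ccL, th$theta_ccM))
  k_cm <- rbinom(n, s_c - k_ccL - k_ccM,
                 cond(1 - th$theta_ccL - th$theta_ccM, th$theta_cm))
  list(n_p = k_mp, n_m = k_pm + k_cm, n_c = k_mc + k_ccL + k_ccM)
}

# Grow all roots' clusters generation by generation until extinction or the
# size cap. n_p/n_m/n_c are counts of pending monomers entered via each
# site; sizes include the root. Returns sizes and a finite flag.
.grow <- function(n_p, n_m, n_c, sizes, th, cap, max_generations = 1e6) {
  n <- length(sizes)
  finite <- rep(NA, n)
  active <- (n_p + n_m + n_c) > 0 & sizes <= cap
  finite[!active & sizes <= cap] <- TRUE
  finite[sizes > cap] <- FALSE
  gen <- 0L
  while (any(active)) {
    gen <- gen + 1L
    if (gen > max_generations) {
      abort("branching-process sampler exceeded the generation cap")
    }
    idx <- which(active)
    # a monomer entered via one site exposes the other two
    s_p <- n_m[idx] + n_c[idx]
    s_m <- n_p[idx] + n_c[idx]
    s_c <- n_p[idx] + n_m[idx]
    off <- .offspring(s_p, s_m, s_c, th)
    n_p[idx] <- off$n_p
    n_m[idx] <- off$n_m
    n_c[idx] <- off$n_c
    sizes[idx] <- sizes[idx] + off$n_p + off$n_m + off$n_c
    over <- idx[sizes[idx] > cap]
    done <- idx[(off$n_p + off$n_m + off$n_c) == 0 & sizes[idx] <= cap]
    finite[over] <- FALSE
    finite[done] <- TRUE
    active[c(over, done)] <- FALSE
  }
  list(sizes = sizes, finite = finite)
}

#' Sample one branching-process cluster
#'
#' Grows the cluster of a single root monomer on the Bethe lattice: each
#' free site bonds with its theta probability to a fresh neighbor entered
#' through the compatible site (p<->m, c<->c, c<->m). Loop-free by
#' construction, matching the tree assumption of the analytic theory.
#'
#' @param theta Bond probabilities (as for [finite_cluster_probability()]).
#' @param cap Size cap; clusters exceeding it are reported as infinite.
#' @param seed Optional RNG seed (caller's RNG state is restored).
#' @return Cluster size (monomers), or `Inf` when the cap was exceeded.
#' @export
sample_branching_cluster <- function(theta, cap = 1e5, seed = NULL) {
  th <- .theta_list(theta)
  stopifnot(cap >= 1)
  .with_seed(seed, {
    root <- .expand_roots(1L, th)
    res <- .grow(root$n_p, root$n_m, root$n_c,
                 sizes = 1 + root$n_p + root$n_m + root$n_c,
                 th = th, cap = cap)
    if (res$finite[1]) res$sizes[1] else Inf
  })
}

# Root expansion: the root monomer has all three sites free. Returns pending
# child counts entered via each site plus, optionally, the b-sum of the
# root's incident edges under a flexibility map.
.expand_roots <- function(n, th, flexibility = NULL) {
  u_p <- runif(n)
  u_m <- runif(n)
  u_c <- runif(n)
  e_pm <- u_p < th$theta_pm                       # child via m
  e_mp <- u_m < th$theta_mp                       # child via p
  e_mc <- !e_mp & u_m < th$theta_mp + th$theta_mc # child via c
  e_ccL <- u_c < th$theta_ccL                     # child via c
  e_ccM <- !e_ccL & u_c < th$theta_ccL + th$theta_ccM
  e_cm <- !e_ccL & !e_ccM &
    u_c < th$theta_ccL + th$theta_ccM + th$theta_cm # child via m
  out <- list(
    n_p = as.integer(e_mp),
    n_m = as.integer(e_pm) + as.integer(e_cm),
    n_c = as.integer(e_mc) + as.integer(e_ccL) + as.integer(e_ccM)
  )
  if (!is.null(flexibility)) {
    fx <- flexibility
    out$b_sum <- fx$b_pm * (e_pm + e_mp) + fx$b_cm * (e_mc + e_cm) +
      fx$b_cLc * e_ccL + fx$b_cMc * e_ccM
  }
  out
}

#' Empirical finite-cluster probability by Monte Carlo
#'
#' Samples `n_roots` independent clusters and reports the fraction whose
#' size stays below the cap, with its binomial standard error. The size cap
#' makes the estimate a one-sided overestimate of finiteness; the reported
#' `bias_bound` is the fraction of finite clusters already larger than a
#' tenth of the cap, a proxy for the probability mass of finite clusters
#' beyond it.
#'
#' @inheritParams sample_branching_cluster
#' @param n_roots Number of sampled roots (>= 1000).
#' @return A one-row tibble: `ps_hat`, `se`, `n_roots`, `cap`,
#'   `bias_bound`, `seed` (NA when run on the ambient RNG stream).
#' @export
empirical_ps <- function(theta, n_roots = 1e4, cap = 1e5, seed = NULL) {
  th <- .theta_list(theta)
  stopifnot(n_roots >= 1000, cap >= 1)
  .with_seed(seed, {
    roots <- .expand_roots(n_roots, th)
    res <- .grow(roots$n_p, roots$n_m, roots$n_c,
                 sizes = 1 + roots$n_p + roots$n_m + roots$n_c,
                 th = th, cap = cap)
    p_hat <- mean(res$finite)
    fin_sizes <- res$sizes[res$finite]
    bias <- if (length(fin_sizes)) mean(fin_sizes > cap / 10) else 0
    tibble(
      ps_hat = p_hat,
      se = sqrt(p_hat * (1 - p_hat) / n_roots),
      n_roots = n_roots,
      cap = cap,
      bias_bound = bias,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  })
}

#' Empirical Maxwell count on the giant cluster
#'
#' Estimates the floppy modes per monomer of the infinite cluster from
#' simulation, without using the analytic weights: the root of a cluster
#' conditioned to exceed the size cap is distributed as a uniformly chosen
#' gel monomer, so averaging half the flexibility-weighted sum of the
#' root's incident bonds over such clusters estimates the Maxwell
#' constraint count per gel monomer. This conditioning-by-simulation makes
#' the estimator free of the frontier (truncation) bias a whole-cluster
#' edge count would have.
#'
#' @inheritParams empirical_ps
#' @param flexibility A [flexibility_map()].
#' @return A one-row tibble: `f_hat`, `se`, `n_gel_roots`, `n_roots`,
#'   `cap`, `seed`. Errors when the process is subcritical (no gel).
#' @export
empirical_maxwell <- function(theta, flexibility, n_roots = 1e4, cap = 1e5,
                              seed = NULL) {
  th <- .theta_list(theta)
  stopifnot(inherits(flexibility, "flexibility_map"), n_roots >= 1000)
  if (!finite_cluster_probability(th)$gel) {
    abort("empirical_maxwell requires a supercritical (gel-forming) theta")
  }
  .with_seed(seed, {
    roots <- .expand_roots(n_roots, th, flexibility = flexibility)
    res <- .grow(roots$n_p, roots$n_m, roots$n_c,
                 sizes = 1 + roots$n_p + roots$n_m + roots$n_c,
                 th = th, cap = cap)
    gel <- !res$finite
    k <- sum(gel)
    if (k < 2) abort("no clusters exceeded the cap; increase n_roots or lower cap")
    b_gel <- roots$b_sum[gel]
    tibble(
      f_hat = 6 - 0.5 * mean(b_gel),
      se = 0.5 * sd(b_gel) / sqrt(k),
      n_gel_roots = k,
      n_roots = n_roots,
      cap = cap,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  })
}

#' Sample an explicit tree network (edge list)
#'
#' A small, non-vectorized sampler that records every monomer and labeled
#' edge; intended for inspection and for testing the site-compatibility
#' rules (p binds m, c binds c through a linker or motor, c binds m through
#' a brancher; each site used at most once).
#'
#' @inheritParams sample_branching_cluster
#' @param cap Monomer cap; growth stops (flagged truncated) beyond it.
#' @return A list with `edges` (tibble: `from`, `to`, `type` in
#'   pm/cLc/cMc/cBm, `from_site`, `to_site`), `n_monomers`, `truncated`,
#'   `seed`.
#' @export
sample_network <- function(theta, cap = 1000, seed = NULL) {
  th <- .theta_list(theta)
  .with_seed(seed, {
    edges <- list()
    # queue rows: monomer id and the site it was entered through ("" = root)
    queue <- list(list(id = 1L, entry = ""))
    n_mono <- 1L
    truncated <- FALSE
    while (length(queue) > 0 && !truncated) {
      cur <- queue[[1]]
      queue <- queue[-1]
      free_sites <- setdiff(c("p", "m", "c"), cur$entry)
      for (site in free_sites) {
        if (n_mono >= cap) { truncated <- TRUE; break }
        u <- runif(1)
        bond <- NULL
        if (site == "p") {
          if (u < th$theta_pm) bond <- list(type = "pm", to_site = "m")
        } else if (site == "m") {
          if (u < th$theta_mp) bond <- list(type = "pm", to_site = "p")
          else if (u < th$theta_mp + th$theta_mc)
            bond <- list(type = "cBm", to_site = "c")
        } else {
          if (u < th$theta_ccL) bond <- list(type = "cLc", to_site = "c")
          else if (u < th$theta_ccL + th$theta_ccM)
            bond <- list(type = "cMc", to_site = "c")
          else if (u < th$theta_ccL + th$theta_ccM + th$theta_cm)
            bond <- list(type = "cBm", to_site = "m")
        }
        if (!is.null(bond)) {
          n_mono <- n_mono + 1L
          edges[[length(edges) + 1L]] <- tibble(
            from = cur$id, to = n_mono, type = bond$type,
            from_site = site, to_site = bond$to_site
          )
          queue[[length(queue) + 1L]] <- list(id = n_mono,
                                              entry = bond$to_site)
        }
      }
    }
    edges <- if (length(edges)) dplyr::bind_rows(edges) else
      tibble(from = integer(), to = integer(), type = character(),
             from_site = character(), to_site = character())
    list(edges = edges, n_monomers = n_mono, truncated = truncated,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}
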