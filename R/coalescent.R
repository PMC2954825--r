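#' Demographic model for the coalescent engine
#'
#' Time is measured backwards from the present in units of `2 * N_ref`
#' generations; population sizes are relative to `N_ref`. Exponential growth
#' rates are per time unit (a forward per-generation rate `r` corresponds to
#' `alpha = r * 2 * N_ref`). Migration rates are per lineage per time unit
#' (a per-generation fraction `m` corresponds to `M = m * 2 * N_ref`).
#' Events (`kind` in `"join"`, `"size"`, `"growth"`, `"migration"`) are
#' applied in time order; a `"join"` moves all lineages of deme `from` into
#' deme `to` and deactivates `from`.
#'
#' @param labels deme labels.
#' @param sizes0 relative deme sizes at time 0.
#' @param growth0 growth rates at time 0 (per time unit).
#' @param mig0 migration matrix at time 0 (`M[i, j]` = backward rate of a
#'   lineage in deme `i` moving to deme `j`).
#' @param events list of event lists, each with `time`, `kind`, and fields
#'   `from`/`to` (join), `deme`/`size`/`growth` (size, growth), or
#'   `from`/`to`/`rate` or `matrix` (migration).
#' @param N_ref reference effective size (diploid) used for unit conversion.
#' @param gen_years generation time in years (used only to convert times to
#'   years in reports).
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(labels, sizes0, growth0 = rep(0, length(labels)),
                              mig0 = matrix(0, length(labels), length(labels)),
                              events = list(), N_ref = 1e4, gen_years = 25) {
  stopifnot(length(sizes0) == length(labels), all(sizes0 > 0))
  tt <- vapply(events, `[[`, numeric(1), "time")
  events <- events[order(tt)]
  structure(list(labels = labels, sizes0 = as.numeric(sizes0),
                 growth0 = as.numeric(growth0), mig0 = mig0,
                 events = events, N_ref = N_ref, gen_years = gen_years),
            class = "demographic_model")
}

#' Single-population constant-size model
#'
#' @param size relative size (default 1, i.e. `N = N_ref`).
#' @param N_ref,gen_years see [demographic_model()].
#' @export
constant_model <- function(size = 1, N_ref = 1e4, gen_years = 25) {
  demographic_model("pop", size, N_ref = N_ref, gen_years = gen_years)
}

#' Three-population out-of-Africa demographic null
#'
#' Point estimates of the widely used three-population African/European/Asian
#' joint-SFS model: ancestral size 7310 expanding to 12300 at 8800
#' generations ago; an out-of-Africa bottleneck population of size 2100
#' splitting from the African deme 5600 generations ago; the European and
#' Asian demes splitting 848 generations ago with initial sizes 1000 and 510
#' and forward growth rates 0.004 and 0.0055 per generation; symmetric
#' migration (per generation: Africa-Eurasia 25e-5 before the European/Asian
#' split, then Africa-Europe 3e-5, Africa-Asia 1.9e-5, Europe-Asia 9.6e-5).
#' All parameters are overridable.
#'
#' @param N_A,N_AF,N_B,N_EU0,N_AS0 diploid sizes (ancestral, African,
#'   bottleneck, European at split, Asian at split).
#' @param r_EU,r_AS forward growth rates per generation.
#' @param T_AF,T_B,T_EU_AS event times in generations.
#' @param m_AF_B,m_AF_EU,m_AF_AS,m_EU_AS migration fractions per generation.
#' @param gen_years generation time in years.
#' @return a [demographic_model()] with demes `AF`, `EU`, `AS`.
#' @export
ooa_model <- function(N_A = 7310, N_AF = 12300, N_B = 2100,
                      N_EU0 = 1000, N_AS0 = 510,
                      r_EU = 0.004, r_AS = 0.0055,
                      T_AF = 8800, T_B = 5600, T_EU_AS = 848,
                      m_AF_B = 25e-5, m_AF_EU = 3e-5, m_AF_AS = 1.9e-5,
                      m_EU_AS = 9.6e-5, gen_years = 25) {
  unit <- 2 * N_A                       # generations per time unit
  t1 <- T_EU_AS / unit; t2 <- T_B / unit; t3 <- T_AF / unit
  sizes0 <- c(AF = N_AF / N_A,
              EU = N_EU0 * exp(r_EU * T_EU_AS) / N_A,
              AS = N_AS0 * exp(r_AS * T_EU_AS) / N_A)
  growth0 <- c(0, r_EU * unit, r_AS * unit)
  M <- matrix(0, 3, 3, dimnames = list(c("AF", "EU", "AS"), c("AF", "EU", "AS")))
  M["AF", "EU"] <- M["EU", "AF"] <- m_AF_EU * unit
  M["AF", "AS"] <- M["AS", "AF"] <- m_AF_AS * unit
  M["EU", "AS"] <- M["AS", "EU"] <- m_EU_AS * unit
  events <- list(
    list(time = t1, kind = "join", from = "AS", to = "EU"),
    list(time = t1, kind = "size", deme = "EU", size = N_B / N_A, growth = 0),
    list(time = t1, kind = "migration",
         matrix = {
           M2 <- matrix(0, 3, 3, dimnames = dimnames(M))
           M2["AF", "EU"] <- M2["EU", "AF"] <- m_AF_B * unit
           M2
         }),
    list(time = t2, kind = "join", from = "EU", to = "AF"),
    list(time = t2, kind = "migration", matrix = matrix(0, 3, 3)),
    list(time = t3, kind = "size", deme = "AF", size = 1, growth = 0))
  demographic_model(c("AF", "EU", "AS"), sizes0, growth0, M, events,
                    N_ref = N_A, gen_years = gen_years)
}

#' Simulation configuration
#'
#' @param n named integer vector of sampled chromosomes per deme (names must
#'   match the model's deme labels), or a single integer for single-deme
#'   models.
#' @param L locus length in bp.
#' @param rho_per_bp recombination rate per bp; by default interpreted as
#'   the population-scaled rate `4 N r` per bp (the ms parameterization);
#'   set `rho_unit = "per_gen"` to give the per-generation rate `r`, which
#'   is then scaled by `4 * N_ref`.
#' @param rho_unit `"4Nr"` or `"per_gen"`.
#' @param S_condition total number of segregating sites to condition on
#'   (exactly this many mutations are placed); `NULL` to use `theta`.
#' @param theta population-scaled mutation rate `4 N mu` for the whole locus
#'   (Poisson number of mutations) when `S_condition` is `NULL`.
#' @param outgroup_scale length of the divergence stem branch, in units of
#'   `2 N_ref` generations (see [add_outgroup_divergence()]).
#' @param n_reps default number of replicates for [null_distribution()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n, L = 8794, rho_per_bp = 1e-6, rho_unit = c("4Nr", "per_gen"),
                       S_condition = NULL, theta = NULL, outgroup_scale = 0,
                       n_reps = 10000) {
  rho_unit <- match.arg(rho_unit)
  if (sum(n) < 2) stop("need at least 2 sampled chromosomes")
  if (L <= 0) stop("locus length must be positive")
  if (!is.null(S_condition) && S_condition < 0) stop("S_condition must be >= 0")
  structure(list(n = n, L = L, rho_per_bp = rho_per_bp, rho_unit = rho_unit,
                 S_condition = S_condition, theta = theta,
                 outgroup_scale = outgroup_scale, n_reps = n_reps),
            class = "sim_config")
}

# total scaled recombination rate (4Nr across the locus), per model units
rho_locus <- function(config, model) {
  r <- config$rho_per_bp * config$L
  if (config$rho_unit == "per_gen") r <- r * 4 * model$N_ref
  r
}

#' Simulate one ancestral recombination graph under the model
#'
#' Event-driven structured-coalescent simulation. Lineages carry their
#' ancestral material as intervals of the unit locus; coalescence merges
#' overlapping intervals into new tree nodes (recorded as tskit-style edges
#' `(child, parent, left, right)`), recombination splits a lineage at a
#' uniform breakpoint, and migration moves lineages between demes. A locus
#' region is retired once its marginal tree reaches the MRCA of all samples.
#' With `rho = 0` the result is a single marginal tree.
#'
#' @param config a [sim_config()].
#' @param model a [demographic_model()].
#' @return object of class `genealogy`: `node_time` (samples first, time 0),
#'   `edges` (matrix with columns child, parent, left, right), `n`,
#'   `sample_deme`, `tmrca`, `total_length` (sum of branch length x span,
#'   in units of 2N generations), `n_recomb`.
#' @export
simulate_genealogy <- function(config, model) {
  labs <- model$labels
  npop <- length(labs)
  nvec <- config$n
  if (is.null(names(nvec))) {
    if (npop != 1L && length(nvec) != npop)
      stop("config$n must be named by deme for multi-deme models")
    nvec <- stats::setNames(rep_len(nvec, npop), labs)
  } else nvec <- stats::setNames(as.integer(nvec[labs]), labs)
  nvec[is.na(nvec)] <- 0L
  n <- sum(nvec)
  rho <- rho_locus(config, model)

  # deme state
  x_ref <- model$sizes0; alpha <- model$growth0; t_ref <- rep(0, npop)
  M <- model$mig0
  events <- model$events; ev_i <- 1L

  # lineage state
  segs <- vector("list", n)
  deme <- integer(n)
  idx <- 1L
  for (p in seq_len(npop)) {
    for (k in seq_len(nvec[p])) {
      segs[[idx]] <- matrix(c(0, 1, idx, 1), nrow = 1,
                            dimnames = list(NULL, c("l", "r", "node", "ns")))
      deme[idx] <- p
      idx <- idx + 1L
    }
  }
  node_time <- numeric(2L * n)
  node_time[seq_len(n)] <- 0
  next_node <- n + 1L
  # edge buffers
  cap <- 8L * n
  e_c <- integer(cap); e_p <- integer(cap); e_l <- numeric(cap); e_r <- numeric(cap)
  n_e <- 0L
  push_edge <- function(child, parent, l, r) {
    if (n_e == cap) {
      cap <<- 2L * cap
      length(e_c) <<- cap; length(e_p) <<- cap
      length(e_l) <<- cap; length(e_r) <<- cap
    }
    n_e <<- n_e + 1L
    e_c[n_e] <<- child; e_p[n_e] <<- parent; e_l[n_e] <<- l; e_r[n_e] <<- r
  }

  t <- 0
  n_recomb <- 0L
  while (length(segs) > 1L) {
    k_by <- tabulate(deme, npop)
    # candidate coalescence time per deme
    tau_c <- rep(Inf, npop); pick_deme <- NA_integer_
    for (p in seq_len(npop)) {
      kp <- k_by[p]
      if (kp < 2L) next
      C <- kp * (kp - 1) / 2
      xc <- x_ref[p] * exp(-alpha[p] * (t - t_ref[p]))
      E <- stats::rexp(1)
      if (alpha[p] == 0) tau_c[p] <- E * xc / C
      else {
        arg <- 1 + alpha[p] * xc * E / C
        tau_c[p] <- if (arg <= 0) Inf else log(arg) / alpha[p]
      }
    }
    # migration
    out_rate <- rowSums(M)
    Rm <- sum(k_by * out_rate)
    tau_m <- if (Rm > 0) stats::rexp(1, Rm) else Inf
    # recombination
    w <- vapply(segs, function(s) s[nrow(s), 2] - s[1, 1], numeric(1))
    Rr <- 0.5 * rho * sum(w)
    tau_r <- if (Rr > 0) stats::rexp(1, Rr) else Inf

    tau <- min(c(tau_c, tau_m, tau_r))
    t_next_ev <- if (ev_i <= length(events)) events[[ev_i]]$time else Inf
    if (t + tau >= t_next_ev) {
      t <- t_next_ev
      ev <- events[[ev_i]]; ev_i <- ev_i + 1L
      if (ev$kind == "join") {
        from <- match(ev$from, labs); to <- match(ev$to, labs)
        deme[deme == from] <- to
        M[from, ] <- 0; M[, from] <- 0
      } else if (ev$kind == "size") {
        p <- match(ev$deme, labs)
        x_ref[p] <- ev$size; t_ref[p] <- t
        alpha[p] <- if (is.null(ev$growth)) 0 else ev$growth
      } else if (ev$kind == "growth") {
        p <- match(ev$deme, labs)
        x_ref[p] <- x_ref[p] * exp(-alpha[p] * (t - t_ref[p]))
        t_ref[p] <- t; alpha[p] <- ev$growth
      } else if (ev$kind == "migration") {
        if (!is.null(ev$matrix)) M <- ev$matrix
        else M[match(ev$from, labs), match(ev$to, labs)] <- ev$rate
      } else stop("unknown event kind: ", ev$kind)
      next
    }
    t <- t + tau
    which_min <- which.min(c(tau_c, tau_m, tau_r))
    if (which_min <= npop) {
      # coalescence in deme which_min
      p <- which_min
      pair <- sample(which(deme == p), 2L)
      a <- segs[[pair[1]]]; b <- segs[[pair[2]]]
      merged <- merge_segments(a, b, t, n, next_node, push_edge)
      if (!is.null(merged$node_used)) {
        node_time[next_node] <- t
        if (next_node == length(node_time)) length(node_time) <- 2L * next_node
        next_node <- next_node + 1L
      }
      segs <- segs[-pair]; deme <- deme[-pair]
      if (nrow(merged$segs) > 0L) {
        segs[[length(segs) + 1L]] <- merged$segs
        deme[length(segs)] <- p
      }
    } else if (which_min == npop + 1L) {
      # migration: pick source deme, lineage, destination
      pr_d <- k_by * out_rate
      p <- sample.int(npop, 1L, prob = pr_d)
      in_p <- which(deme == p)
      lin <- in_p[sample.int(length(in_p), 1L)]
      dest <- sample.int(npop, 1L, prob = M[p, ])
      deme[lin] <- dest
    } else {
      # recombination
      lin <- sample.int(length(segs), 1L, prob = w)
      s <- segs[[lin]]
      bp <- stats::runif(1, s[1, 1], s[nrow(s), 2])
      left <- s[s[, 2] <= bp, , drop = FALSE]
      right <- s[s[, 1] >= bp, , drop = FALSE]
      strad <- which(s[, 1] < bp & s[, 2] > bp)
      if (length(strad)) {
        row <- s[strad[1], ]
        lrow <- row; lrow[2] <- bp
        rrow <- row; rrow[1] <- bp
        left <- rbind(left, lrow, deparse.level = 0)
        right <- rbind(rrow, right, deparse.level = 0)
      }
      if (nrow(left) == 0L || nrow(right) == 0L) next  # degenerate split
      n_recomb <- n_recomb + 1L
      segs[[lin]] <- left
      segs[[length(segs) + 1L]] <- right
      deme[length(segs)] <- deme[lin]
    }
  }

  edges <- cbind(child = e_c[seq_len(n_e)], parent = e_p[seq_len(n_e)],
                 left = e_l[seq_len(n_e)], right = e_r[seq_len(n_e)])
  node_time <- node_time[seq_len(next_node - 1L)]
  blen <- (node_time[edges[, "parent"]] - node_time[edges[, "child"]]) *
    (edges[, "right"] - edges[, "left"])
  sample_deme <- integer(n)
  idx <- 1L
  for (p in seq_len(npop)) {
    if (nvec[p] > 0) sample_deme[idx:(idx + nvec[p] - 1L)] <- p
    idx <- idx + nvec[p]
  }
  structure(list(node_time = node_time, edges = edges, n = n,
                 sample_deme = stats::setNames(sample_deme, NULL),
                 tmrca = max(node_time), total_length = sum(blen),
                 n_recomb = n_recomb),
            class = "genealogy")
}

# Merge two segment lists at a coalescence event. Returns carried-forward
# segments and whether the new node id was used. Edges for overlapping
# material are recorded through push_edge; spans whose merged node covers all
# n samples are complete and not carried forward.
merge_segments <- function(a, b, t, n, new_node, push_edge) {
  bps <- sort(unique(c(a[, 1], a[, 2], b[, 1], b[, 2])))
  out <- matrix(0, nrow = 0, ncol = 4,
                dimnames = list(NULL, c("l", "r", "node", "ns")))
  used <- NULL
  add_seg <- function(l, r, node, ns) {
    # adjacent spans may share the new node yet differ in descendant count
    # across a recombination boundary; compress only when ns matches too
    if (nrow(out) && out[nrow(out), 3] == node && out[nrow(out), 4] == ns &&
        out[nrow(out), 2] == l)
      out[nrow(out), 2] <<- r
    else out <<- rbind(out, c(l, r, node, ns))
  }
  for (k in seq_len(length(bps) - 1L)) {
    l <- bps[k]; r <- bps[k + 1L]
    ia <- which(a[, 1] <= l & a[, 2] >= r)
    ib <- which(b[, 1] <= l & b[, 2] >= r)
    if (length(ia) && length(ib)) {
      used <- new_node
      push_edge(a[ia, 3], new_node, l, r)
      push_edge(b[ib, 3], new_node, l, r)
      ns <- a[ia, 4] + b[ib, 4]
      if (ns < n) add_seg(l, r, new_node, ns)
    } else if (length(ia)) {
      add_seg(l, r, a[ia, 3], a[ia, 4])
    } else if (length(ib)) {
      add_seg(l, r, b[ib, 3], b[ib, 4])
    }
  }
  list(segs = out, node_used = used)
}

#' Place mutations on a simulated genealogy
#'
#' Infinite-sites mutation placement. With `S` given, exactly `S` mutations
#' are placed, each on a branch chosen with probability proportional to
#' branch length x span (fixed-S conditioning by direct placement). With
#' `theta` given, the number of mutations is Poisson with mean
#' `theta / 2 * total_length`. Positions are uniform within the chosen
#' edge's span; carriers are the samples below the edge's child node at that
#' position.
#'
#' @param gen a [simulate_genealogy()] result.
#' @param S exact number of segregating sites, or `NULL`.
#' @param theta scaled mutation rate (used when `S` is `NULL`).
#' @return object of class `sim_replicate`: 0/1 haplotype matrix (columns in
#'   position order), `positions` in (0, 1], `branch` (edge index per site),
#'   the generating `genealogy`, and `fd = 0` (see
#'   [add_outgroup_divergence()]).
#' @export
place_mutations <- function(gen, S = NULL, theta = NULL) {
  blen <- (gen$node_time[gen$edges[, "parent"]] -
             gen$node_time[gen$edges[, "child"]]) *
    (gen$edges[, "right"] - gen$edges[, "left"])
  tot <- sum(blen)
  if (is.null(S)) {
    if (is.null(theta)) stop("give S or theta")
    S <- stats::rpois(1, theta / 2 * tot)
  }
  S <- as.integer(S)
  if (S > 0 && tot <= 0) stop("zero total branch length")
  mat <- matrix(0L, gen$n, S)
  pos <- numeric(S)
  branch <- integer(S)
  if (S > 0) {
    by_parent <- split(seq_len(nrow(gen$edges)), gen$edges[, "parent"])
    eidx <- sample.int(length(blen), S, replace = TRUE, prob = blen)
    for (s in seq_len(S)) {
      e <- eidx[s]
      u <- stats::runif(1, gen$edges[e, "left"], gen$edges[e, "right"])
      pos[s] <- u
      branch[s] <- e
      mat[descendant_samples(gen, by_parent, gen$edges[e, "child"], u), s] <- 1L
    }
    ord <- order(pos)
    mat <- mat[, ord, drop = FALSE]; pos <- pos[ord]; branch <- branch[ord]
  }
  structure(list(mat = mat, positions = pos, branch = branch,
                 genealogy = gen, fd = 0L, fd_positions = numeric(0),
                 outgroup = rep(0L, S)),
            class = "sim_replicate")
}

descendant_samples <- function(gen, by_parent, node, pos) {
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= gen$n) { out <- c(out, v); next }
    es <- by_parent[[as.character(v)]]
    es <- es[gen$edges[es, "left"] <= pos & gen$edges[es, "right"] > pos]
    stack <- c(stack, gen$edges[es, "child"])
  }
  out
}

#' Add outgroup divergence to a replicate
#'
#' Accumulates mutations on a stem/outgroup branch of total scaled length
#' `outgroup_scale` (units of 2N generations). Under fixed-S conditioning
#' the implied per-unit mutation rate is `S / total_length`, so the number
#' of fixed differences is Poisson with mean
#' `outgroup_scale * S / total_length`; doubling the scale doubles the
#' expectation. Fixed differences never overlap polymorphic sites
#' (infinite sites; positions are continuous).
#'
#' @param rep a [place_mutations()] replicate.
#' @param outgroup_scale non-negative stem length.
#' @param mu_unit optional explicit mutation rate per time unit for the
#'   whole locus (overrides the implied rate; needed when `S = 0`).
#' @return the replicate with `fd`, `fd_positions` filled.
#' @export
add_outgroup_divergence <- function(rep, outgroup_scale, mu_unit = NULL) {
  if (outgroup_scale < 0) stop("negative outgroup scale")
  S <- ncol(rep$mat)
  mu <- if (!is.null(mu_unit)) mu_unit
        else if (S > 0) S / rep$genealogy$total_length
        else 0
  lambda <- outgroup_scale * mu
  fd <- stats::rpois(1, lambda)
  rep$fd <- fd
  rep$fd_positions <- sort(stats::runif(fd))
  rep
}

#' Calibrate the outgroup branch to a target SNP/fixed-difference ratio
#'
#' Finds the stem-branch length such that the expected simulated ratio of
#' segregating sites to fixed differences matches `target_ratio`. Under
#' fixed-S conditioning `E[FD] = scale * S * E[1/total_length]`, linear in
#' the scale, so a proportional update converges in a few batches; iteration
#' stops when a fresh batch estimate is within `tol` (relative) of the
#' target.
#'
#' @param config a [sim_config()] with `S_condition` set.
#' @param model a [demographic_model()].
#' @param target_ratio target SNPs per fixed difference (> 0).
#' @param batch replicates per batch.
#' @param tol relative tolerance on the achieved ratio.
#' @param max_iter maximum number of batches.
#' @return list with `outgroup_scale`, `achieved_ratio`, `iterations`.
#' @export
calibrate_divergence <- function(config, model, target_ratio, batch = 200,
                                 tol = 0.05, max_iter = 12) {
  if (target_ratio <= 0) stop("target ratio must be positive")
  S <- config$S_condition
  if (is.null(S) || S <= 0) stop("calibration needs fixed-S conditioning")
  inv_len <- replicate(batch, {
    g <- simulate_genealogy(config, model)
    1 / g$total_length
  })
  scale <- 1 / (target_ratio * mean(inv_len))   # solves S/E[FD] = target
  for (it in seq_len(max_iter)) {
    fd <- replicate(batch, {
      g <- simulate_genealogy(config, model)
      stats::rpois(1, scale * S / g$total_length)
    })
    achieved <- S / mean(fd)
    if (abs(achieved - target_ratio) / target_ratio <= tol)
      return(list(outgroup_scale = scale, achieved_ratio = achieved,
                  iterations = it))
    scale <- scale * target_ratio / achieved
  }
  stop("calibration did not converge after ", max_iter, " batches")
}

#' Null distributions of summary statistics by simulation
#'
#' Runs `n_reps` coalescent replicates under the configuration and model,
#' evaluates each statistic function on every replicate, and returns the
#' draws (one column per statistic). Statistic functions receive a
#' `sim_replicate`.
#'
#' @param stat_fns named list of functions `function(rep) -> numeric(1)`.
#' @param config a [sim_config()].
#' @param model a [demographic_model()].
#' @param n_reps number of replicates (defaults to `config$n_reps`).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the draw matrix is reproducible.
#' @return matrix `n_reps x length(stat_fns)` of class `null_draws`, with
#'   the seed stored as an attribute.
#' @export
null_distribution <- function(stat_fns, config, model,
                              n_reps = config$n_reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(NA_real_, n_reps, length(stat_fns),
                  dimnames = list(NULL, names(stat_fns)))
  for (r in seq_len(n_reps)) {
    g <- simulate_genealogy(config, model)
    rep_ <- place_mutations(g, S = config$S_condition, theta = config$theta)
    if (config$outgroup_scale > 0)
      rep_ <- add_outgroup_divergence(rep_, config$outgroup_scale)
    for (j in seq_along(stat_fns))
      draws[r, j] <- stat_fns[[j]](rep_)
  }
  attr(draws, "seed") <- seed
  class(draws) <- c("null_draws", class(draws))
  draws
}

#' Summary statistics on a simulated replicate
#'
#' Convenience statistic functions for [null_distribution()]:
#' `sim_tajimas_d` computes Tajima's D from the 0/1 matrix; `sim_theta_pi`
#' the mean pairwise difference; `sim_fold_freqs` the folded minor-allele
#' counts per site.
#'
#' @param rep a `sim_replicate`.
#' @name sim_stats
#' @export
sim_tajimas_d <- function(rep) {
  S <- ncol(rep$mat)
  if (S == 0L) return(NA_real_)
  n <- nrow(rep$mat)
  d <- colSums(rep$mat)
  pi <- sum(2 * d * (n - d)) / (n * (n - 1))
  tajimas_d(S, pi, n)
}

#' @rdname sim_stats
#' @export
sim_theta_pi <- function(rep) {
  n <- nrow(rep$mat)
  d <- colSums(rep$mat)
  sum(2 * d * (n - d)) / (n * (n - 1))
}

#' @rdname sim_stats
#' @export
sim_fold_freqs <- function(rep) {
  d <- colSums(rep$mat)
  pmin(d, nrow(rep$mat) - d)
}

#' Write and read ms-compatible replicate text
#'
#' `write_ms` renders replicates in the classic ms block format
#' (`//`, `segsites:`, `positions:`, then one 0/1 row per haplotype);
#' `read_ms` parses that format back into 0/1 matrices.
#'
#' @param reps list of `sim_replicate` objects.
#' @param path output file.
#' @return `write_ms`: the path, invisibly. `read_ms`: list of replicates,
#'   each a list with `mat` and `positions`.
#' @export
write_ms <- function(reps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(reps[[1]]$mat)
  writeLines(sprintf("ms %d %d", n, length(reps)), con)
  writeLines(as.character(sample.int(2^15, 1)), con)  # seed echo line
  for (r in reps) {
    writeLines("", con); writeLines("//", con)
    writeLines(sprintf("segsites: %d", ncol(r$mat)), con)
    if (ncol(r$mat) > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.5f", r$positions), collapse = " ")), con)
      writeLines(apply(r$mat, 1, paste0, collapse = ""), con)
    }
  }
  invisible(path)
}

#' @rdname write_ms
#' @export
read_ms <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    j <- starts[i]
    seg <- as.integer(sub("segsites: *", "", lines[j + 1L]))
    if (seg == 0L) { out[[i]] <- list(mat = matrix(0L, 0, 0), positions = numeric(0)); next }
    pos <- as.numeric(strsplit(sub("positions: *", "", lines[j + 2L]), " +")[[1]])
    rows <- character(0)
    k <- j + 3L
    while (k <= length(lines) && grepl("^[01]+$", lines[k])) {
      rows <- c(rows, lines[k]); k <- k + 1L
    }
    mat <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    out[[i]] <- list(mat = mat, positions = pos)
  }
  out
}
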