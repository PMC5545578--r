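#' Specify a simulated cohort of paired hemispheric networks
#'
#' Generates subjects in three diagnostic groups (NC, MCI, AD) with paired
#' left/right weighted networks, demographic/scanner covariates, and memory
#' scores linearly coupled to the true hemispheric asymmetry. The group sizes
#' and the demographic structure default to the study-cohort layout
#' (48 NC / 95 MCI / 25 AD; group-specific age distributions and sex
#' imbalance, with the AD group strongly male-dominated at 19/6).
#'
#' Each subject's left network is drawn once (edge presence Bernoulli at
#' `density`; weights Gaussian around `base_weight_mean`, clipped into
#' `(0, 1]` like an FA weight); the right network applies an additive shift
#' to the shared edges: a group-level component `global_asym_delta[group]`, a
#' per-subject random component with standard deviation `subject_asym_sd`
#' (giving within-group AI variance, as real cohorts show), and an extra
#' `nodal_asym_delta[group]` on edges incident to `nodal_asym_nodes`.
#' Weights are re-clipped after shifting; the clipping rate is reported in
#' the truth record. With all shift components zero the two hemispheres are
#' bit-identical and every AI is exactly zero.
#'
#' Scores are generated as
#' `score = beta0 + beta_ai * AI_eglob + beta_age * (age - 75) +
#'  beta_sex * male + noise`, with the true AI taken from the realized
#' global-efficiency asymmetry of the subject's two networks.
#'
#' @param n_per_group named integer vector of group sizes (NC, MCI, AD).
#' @param n_nodes nodes per hemisphere (full-template default 512).
#' @param base_weight_mean,base_weight_sd edge-weight distribution.
#' @param density probability that a node pair is connected.
#' @param global_asym_delta named per-group additive right-minus-left shift.
#' @param subject_asym_sd per-subject SD of the random shift component.
#' @param nodal_asym_nodes integer node subset carrying extra nodal shift.
#' @param nodal_asym_delta named per-group extra shift on those nodes' edges.
#' @param covariate_model list of distribution parameters (see defaults).
#' @param score_model per-score coefficient lists (see defaults).
#' @param seed RNG seed; per-subject streams are split deterministically from
#'   it so cohorts are reproducible element-wise.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = c(NC = 48L, MCI = 95L, AD = 25L),
                        n_nodes = 512L,
                        base_weight_mean = 0.45, base_weight_sd = 0.1,
                        density = 0.15,
                        global_asym_delta = c(NC = 0, MCI = 0, AD = 0),
                        subject_asym_sd = 0,
                        nodal_asym_nodes = integer(0),
                        nodal_asym_delta = c(NC = 0, MCI = 0, AD = 0),
                        covariate_model = NULL,
                        score_model = NULL,
                        seed = 1L) {
  groups <- c("NC", "MCI", "AD")
  n_per_group <- unlist(n_per_group)
  global_asym_delta <- unlist(global_asym_delta)
  nodal_asym_delta <- unlist(nodal_asym_delta)
  nodal_asym_nodes <- as.integer(unlist(nodal_asym_nodes))
  if (!is.null(covariate_model))
    covariate_model <- lapply(covariate_model,
                              function(x) if (is.list(x)) unlist(x) else x)
  stopifnot(all(groups %in% names(n_per_group)),
            all(n_per_group >= 0), n_nodes >= 2,
            base_weight_mean > 0, base_weight_mean <= 1,
            base_weight_sd >= 0, density > 0, density <= 1,
            subject_asym_sd >= 0,
            all(groups %in% names(global_asym_delta)),
            all(groups %in% names(nodal_asym_delta)))
  if (length(nodal_asym_nodes) &&
      any(nodal_asym_nodes < 1 | nodal_asym_nodes > n_nodes))
    stop("nodal_asym_nodes out of range")
  if (is.null(covariate_model)) covariate_model <- default_covariate_model()
  if (is.null(score_model)) score_model <- default_score_model()
  n_per_group <- n_per_group[groups]
  storage.mode(n_per_group) <- "integer"
  global_asym_delta <- global_asym_delta[groups]
  storage.mode(global_asym_delta) <- "double"
  nodal_asym_delta <- nodal_asym_delta[groups]
  storage.mode(nodal_asym_delta) <- "double"
  structure(list(n_per_group = n_per_group, n_nodes = as.integer(n_nodes),
                 base_weight_mean = as.numeric(base_weight_mean),
                 base_weight_sd = as.numeric(base_weight_sd),
                 density = as.numeric(density),
                 global_asym_delta = global_asym_delta,
                 subject_asym_sd = as.numeric(subject_asym_sd),
                 nodal_asym_nodes = nodal_asym_nodes,
                 nodal_asym_delta = nodal_asym_delta,
                 covariate_model = covariate_model,
                 score_model = score_model, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default covariate and score models for the cohort generator
#'
#' `default_covariate_model()` returns the demographic/scanner model:
#' group-wise age mean/SD and probability-male matching the study-cohort
#' table, whole-brain ICV around 1.45e6 mm^3 split near-evenly between
#' hemispheres, and site-varying scanner timing (TR ~ 12.5 s, TE ~ 68 ms).
#' `default_score_model()` returns per-score coefficient lists linking the
#' RAVLT-like scores to the true AI (negative `beta_ai`: rightward asymmetry
#' predicts lower memory scores), age, and sex.
#'
#' @return a named list of model parameters; pass a modified copy to
#'   [cohort_spec()] to change the simulation.
#' @export
default_covariate_model <- function() {
  list(age_mean = c(NC = 75.0, MCI = 74.9, AD = 77.4),
       age_sd = c(NC = 6.0, MCI = 7.4, AD = 8.4),
       p_male = c(NC = 21 / 48, MCI = 57 / 95, AD = 19 / 25),
       whole_icv_mean = 1.45e6, whole_icv_sd = 1.3e5,
       left_share_mean = 0.5, left_share_sd = 0.004,
       tr_mean = 12500, tr_sd = 400,   # ms
       te_mean = 68, te_sd = 3)        # ms
}

#' @rdname default_covariate_model
#' @export
default_score_model <- function() {
  list(TOTAL = list(beta0 = 35, beta_ai = -60, beta_age = -0.25,
                    beta_sex = 0, noise_sd = 9),
       TOT6 = list(beta0 = 5, beta_ai = -15, beta_age = -0.08,
                   beta_sex = 0, noise_sd = 3),
       RECOG = list(beta0 = 4, beta_ai = -12, beta_age = -0.08,
                    beta_sex = 0, noise_sd = 3))
}

#' Simulate a cohort of paired hemispheric networks
#'
#' Realizes a [cohort_spec()]. Per-subject RNG streams are derived from the
#' cohort seed by a single `sample.int` draw, so any subject is reproducible
#' independently of the others.
#'
#' @param spec a `cohort_spec`.
#' @param compute_true_ai compute each subject's realized global-efficiency
#'   AI (needed for score generation); disable only when scores are unused.
#' @return a `cohort_sim` object: list with `cohort` (per-subject
#'   data.frame: id, group, age, sex, ICVs, TR, TE, RAVLT scores, true AI),
#'   `networks` (per subject, `left`/`right` [hemispheric_network()]s), and
#'   `truth` (planted deltas, per-subject realized shifts, clip rate, log).
#' @export
simulate_cohort <- function(spec, compute_true_ai = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  n_total <- length(groups)
  stopifnot(n_total > 0)
  subject_seeds <- with_seed(spec$seed,
                             sample.int(.Machine$integer.max - 1L, n_total))
  cm <- spec$covariate_model
  n <- spec$n_nodes
  pairs_i <- which(upper.tri(matrix(0, n, n)))
  npairs <- length(pairs_i)
  nodal_edges <- if (length(spec$nodal_asym_nodes)) {
    ij <- arrayInd(pairs_i, c(n, n))
    ij[, 1] %in% spec$nodal_asym_nodes | ij[, 2] %in% spec$nodal_asym_nodes
  } else rep(FALSE, npairs)

  networks <- vector("list", n_total)
  rows <- vector("list", n_total)
  shifts <- numeric(n_total)
  clipped <- 0; total_w <- 0
  log <- character(0)

  for (s in seq_len(n_total)) {
    g <- groups[s]
    res <- with_seed(subject_seeds[s], {
      age <- stats::rnorm(1, cm$age_mean[g], cm$age_sd[g])
      sex <- if (stats::runif(1) < cm$p_male[g]) "M" else "F"
      whole_icv <- stats::rnorm(1, cm$whole_icv_mean, cm$whole_icv_sd)
      share <- stats::rnorm(1, cm$left_share_mean, cm$left_share_sd)
      left_icv <- share * whole_icv
      right_icv <- whole_icv - left_icv
      tr <- stats::rnorm(1, cm$tr_mean, cm$tr_sd)
      te <- stats::rnorm(1, cm$te_mean, cm$te_sd)

      present <- stats::runif(npairs) < spec$density
      w <- numeric(npairs)
      wraw <- stats::rnorm(sum(present), spec$base_weight_mean,
                           spec$base_weight_sd)
      w[present] <- clip01(wraw)
      delta_s <- spec$global_asym_delta[[g]] +
        if (spec$subject_asym_sd > 0) stats::rnorm(1, 0, spec$subject_asym_sd) else 0
      wr <- w
      wr[present] <- wr[present] + delta_s
      sel <- present & nodal_edges
      wr[sel] <- wr[sel] + spec$nodal_asym_delta[[g]]
      nclip <- sum(wr[present] <= 0 | wr[present] > 1) +
        sum(wraw <= 0 | wraw > 1)
      wr[present] <- clip01(wr[present])
      noise <- stats::rnorm(length(spec$score_model) + 5)  # reserved draws
      list(age = age, sex = sex, whole_icv = whole_icv, left_icv = left_icv,
           right_icv = right_icv, tr = tr, te = te, w = w, wr = wr,
           delta_s = delta_s, nclip = nclip, noise = noise,
           present = present)
    })
    Wl <- matrix(0, n, n); Wl[pairs_i] <- res$w; Wl <- Wl + t(Wl)
    Wr <- matrix(0, n, n); Wr[pairs_i] <- res$wr; Wr <- Wr + t(Wr)
    left <- hemispheric_network(Wl, hemisphere = "left")
    right <- hemispheric_network(Wr, hemisphere = "right")
    if (!is_connected_w(Wl) || !is_connected_w(Wr))
      log <- c(log, sprintf(
        "subject %d: hemispheric network not connected at density %.3g",
        s, spec$density))
    true_ai <- NA_real_
    if (compute_true_ai) {
      eg_l <- global_efficiency(shortest_paths(Wl))
      eg_r <- global_efficiency(shortest_paths(Wr))
      true_ai <- if (eg_l + eg_r > 0) (eg_r - eg_l) / (eg_r + eg_l) else 0
    }
    male <- as.numeric(res$sex == "M")
    sc <- vapply(seq_along(spec$score_model), function(k) {
      b <- spec$score_model[[k]]
      b$beta0 + b$beta_ai * true_ai + b$beta_age * (res$age - 75) +
        b$beta_sex * male + b$noise_sd * res$noise[k]
    }, numeric(1))
    names(sc) <- names(spec$score_model)
    networks[[s]] <- list(left = left, right = right)
    shifts[s] <- res$delta_s
    clipped <- clipped + res$nclip
    total_w <- total_w + 2 * sum(res$present)
    rows[[s]] <- data.frame(
      id = sprintf("S%04d", s), group = g, age = res$age, sex = res$sex,
      whole_icv = res$whole_icv, left_icv = res$left_icv,
      right_icv = res$right_icv, tr = res$tr, te = res$te,
      ravlt_total = sc[["TOTAL"]], ravlt_tot6 = sc[["TOT6"]],
      ravlt_recog = sc[["RECOG"]], true_ai = true_ai)
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  names(networks) <- cohort$id
  if (length(log)) for (msg in unique(log)[1]) warning(msg)
  structure(list(cohort = cohort, networks = networks,
                 truth = list(global_asym_delta = spec$global_asym_delta,
                              nodal_asym_nodes = spec$nodal_asym_nodes,
                              nodal_asym_delta = spec$nodal_asym_delta,
                              subject_shift = shifts,
                              clip_rate = if (total_w > 0) clipped / total_w else 0,
                              log = log),
                 spec = spec),
            class = "cohort_sim")
}

clip01 <- function(x) pmin(pmax(x, .Machine$double.eps), 1)

is_connected_w <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  igraph::is_connected(g)
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d subjects (%s), %d nodes/hemisphere\n",
              nrow(x$cohort),
              paste(names(table(x$cohort$group)),
                    table(x$cohort$group), collapse = " ", sep = ":"),
              x$spec$n_nodes))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One whitespace-delimited weight-matrix file per subject-hemisphere plus a
#' tab-separated covariate/score table.
#'
#' @param sim a `cohort_sim`.
#' @param dir output directory.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (id in names(sim$networks)) {
    write_network(sim$networks[[id]]$left,
                  file.path(dir, sprintf("%s_left.txt", id)))
    write_network(sim$networks[[id]]$right,
                  file.path(dir, sprintf("%s_right.txt", id)))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cohort <- utils::read.table(file.path(dir, "cohort.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  networks <- lapply(cohort$id, function(id) {
    list(left = read_network(file.path(dir, sprintf("%s_left.txt", id)),
                             hemisphere = "left"),
         right = read_network(file.path(dir, sprintf("%s_right.txt", id)),
                              hemisphere = "right"))
  })
  names(networks) <- cohort$id
  structure(list(cohort = cohort, networks = networks, truth = NULL,
                 spec = NULL), class = "cohort_sim")
}
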