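#' Run the full synthetic study on a cohort of simulated subjects
#'
#' For each subject: generate coordinates and a planted structural network,
#' rebuild the navigation-game network and classify edges, generate a
#' rest/task functional pair, fit the spectral map under the three
#' structural masks (all / optimal / nonoptimal) for each state, and score
#' every prediction by upper-triangle correlation and by the Betti-0
#' persistence score. Per-subject sub-seeds are derived from the master seed
#' by a fixed splitting rule, so the whole cohort is reproducible.
#'
#' @param config list with elements \code{n_subjects}, \code{n_nodes},
#'   \code{k} (polynomial order), \code{noise_sd}, \code{p_extra},
#'   \code{p_drop}, \code{seed}; missing entries take the defaults of
#'   \code{cohort_config()}
#' @param verbose print one log line per subject/stage
#' @return object of class \code{cohort_result}: \code{results} (tidy
#'   long-format data.frame: subject, condition, metric, value) and
#'   \code{config}
#' @export
run_cohort <- function(config = cohort_config(), verbose = FALSE) {
  cfg <- utils::modifyList(cohort_config(), config)
  stopifnot(cfg$n_subjects >= 1, cfg$n_nodes >= 4)
  a <- default_poly_coef(cfg$k)
  rows <- list()
  add <- function(subject, condition, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subject, condition = condition, metric = metric,
      value = value)
  for (s in seq_len(cfg$n_subjects)) {
    sseed <- subject_seed(cfg$seed, s)
    if (verbose) message(sprintf("[cohort] subject %d (seed %d)", s, sseed))
    coords <- gen_coords(cfg$n_nodes, sseed, "uniform_box")
    planted <- gen_structural(coords, cfg$p_extra, cfg$p_drop, sseed + 1L)
    cls <- classify_edges(planted$structural, planted$nng_truth)
    add(s, "structure", "optimality", cls$optimality)
    add(s, "structure", "M", cls$M_count)
    add(s, "structure", "F", cls$F_count)
    if (!any(planted$nonoptimal_mask)) {
      # unperturbed cohort: no nonoptimal class, no rest/task dissociation
      # to generate; rest is the forward model on the full (optimal) matrix
      F_rest <- gen_functional(planted$structural, a, "identity",
                               cfg$noise_sd, sseed + 2L)
      fc <- list(rest = F_rest)
    } else {
      fc <- gen_rest_task_pair(planted, a, cfg$noise_sd, sseed + 2L)
    }
    for (state in names(fc)) {
      F_real <- fc[[state]]
      masks <- if (any(planted$nonoptimal_mask))
        c("all", "optimal", "nonoptimal") else c("all", "optimal")
      for (msk in masks) {
        S_in <- mask_structural(planted$structural, cls, msk)
        model <- fit_spectral_map(S_in, F_real, cfg$k)
        F_hat <- predict_fc(model, S_in)
        cond <- paste(state, msk, sep = "_")
        add(s, cond, "r", score_correlation(F_hat, F_real))
        add(s, cond, "sse_beta", sse_beta(F_real, F_hat))
      }
    }
  }
  structure(list(results = do.call(rbind, rows), config = cfg),
            class = "cohort_result")
}

#' Default cohort configuration
#'
#' @return named list of defaults: 10 subjects, 40 nodes, order-5
#'   polynomial, noiseless forward model, 30% planted long-range edges, no
#'   dropped game edges, master seed 1
#' @export
cohort_config <- function() {
  list(n_subjects = 10L, n_nodes = 40L, k = 5L, noise_sd = 0,
       p_extra = 0.3, p_drop = 0, seed = 1L)
}

#' Per-subject sub-seed from a master seed (fixed splitting rule)
#'
#' @param seed master seed
#' @param subject subject index
#' @return integer seed below 2^31
#' @export
subject_seed <- function(seed, subject) {
  as.integer((as.numeric(seed) * 7919 + subject * 104729) %% 2147483647)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("cohort:", x$config$n_subjects, "subjects,", x$config$n_nodes,
      "nodes\n")
  agg <- stats::aggregate(value ~ condition + metric, x$results, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Reshape a cohort metric into a subjects x conditions matrix
#'
#' @param cohort a \code{cohort_result}
#' @param metric metric name, e.g. "r" or "sse_beta"
#' @param conditions which conditions (columns) to keep, in order
#' @return numeric matrix, rows = subjects
#' @export
score_matrix <- function(cohort, metric = "r",
                         conditions = c("rest_all", "rest_optimal",
                                        "rest_nonoptimal")) {
  df <- cohort$results[cohort$results$metric == metric &
                         cohort$results$condition %in% conditions, ]
  wide <- stats::reshape(df[, c("subject", "condition", "value")],
                         idvar = "subject", timevar = "condition",
                         direction = "wide")
  M <- as.matrix(wide[, paste0("value.", conditions), drop = FALSE])
  colnames(M) <- conditions
  rownames(M) <- wide$subject
  M
}

#' Compare prediction scores across conditions
#'
#' Group statistics as used for prediction-accuracy comparisons: a one-way
#' repeated-measures ANOVA with Greenhouse-Geisser sphericity correction and
#' Bonferroni-adjusted pairwise post hoc tests, or paired / two-sample
#' t-tests.
#'
#' @param scores numeric matrix, rows = subjects, columns = conditions (two
#'   columns for the t designs)
#' @param design "repeated_anova", "paired_t" or "two_sample_t"
#' @return list; for the ANOVA design: \code{F}, \code{df}, \code{gg_epsilon},
#'   \code{p_gg} (Greenhouse-Geisser corrected), \code{posthoc} (Bonferroni
#'   pairwise p matrix); for t designs the \code{htest} plus \code{t},
#'   \code{p}. Zero within-pair variance in a paired design is flagged with
#'   \code{degenerate = TRUE} and a maximal statistic.
#' @export
compare_scores <- function(scores,
                           design = c("repeated_anova", "paired_t",
                                      "two_sample_t")) {
  design <- match.arg(design)
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("incomplete rows in the score matrix")
  nc <- ncol(scores)
  if (design == "repeated_anova") {
    stopifnot(nrow(scores) >= 3, nc >= 2)
    if (all(apply(scores, 1, function(r) max(r) - min(r)) == 0))
      return(list(F = 0, df = c(nc - 1, (nrow(scores) - 1) * (nc - 1)),
                  gg_epsilon = 1, p_gg = 1,
                  posthoc = matrix(1, nc, nc,
                                   dimnames = list(colnames(scores),
                                                   colnames(scores)))))
    idata <- data.frame(condition = factor(colnames(scores),
                                           levels = colnames(scores)))
    mlm <- stats::lm(scores ~ 1)
    aov_res <- car::Anova(mlm, idata = idata, idesign = ~condition,
                          type = "III")
    s <- summary(aov_res, multivariate = FALSE)
    uni <- s$univariate.tests
    Fval <- uni["condition", "F value"]
    dfs <- c(uni["condition", "num Df"], uni["condition", "den Df"])
    adj <- s$pval.adjustments
    gg_eps <- unname(adj["condition", "GG eps"])
    p_gg <- unname(adj["condition", "Pr(>F[GG])"])
    long <- data.frame(
      value = as.vector(scores),
      condition = factor(rep(colnames(scores), each = nrow(scores)),
                         levels = colnames(scores)),
      subject = factor(rep(seq_len(nrow(scores)), nc)))
    ph <- stats::pairwise.t.test(long$value, long$condition, paired = TRUE,
                                 p.adjust.method = "bonferroni")
    list(F = unname(Fval), df = unname(dfs), gg_epsilon = gg_eps,
         p_gg = p_gg, posthoc = ph$p.value)
  } else if (design == "paired_t") {
    stopifnot(nc == 2)
    dif <- scores[, 1] - scores[, 2]
    if (stats::sd(dif) == 0) {
      return(list(t = sign(mean(dif)) * Inf,
                  p = if (mean(dif) == 0) 1 else 0, degenerate = TRUE))
    }
    ht <- stats::t.test(scores[, 1], scores[, 2], paired = TRUE)
    list(t = unname(ht$statistic), p = ht$p.value, htest = ht,
         degenerate = FALSE)
  } else {
    stopifnot(nc == 2)
    ht <- stats::t.test(scores[, 1], scores[, 2])
    list(t = unname(ht$statistic), p = ht$p.value, htest = ht,
         degenerate = FALSE)
  }
}
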