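#' Scenario configuration for end-to-end simulation experiments
#'
#' Captures one cell of the simulation design: trait type, heritability,
#' polygenicity, genetic architecture (single-class GA1, three-class mixture
#' GA2, or the two-causal region design), prevalence for binary traits, and
#' the cohort dimensions. The canonical grid is h2 in \{0.1, 0.3\}, causal
#' proportion in \{0.001, 0.01\}, architecture GA1/GA2, prevalence in
#' \{0.05, 0.15\}; the two-causal grid crosses configuration LL/LS/SS with
#' n in \{200k, 250k, 300k\}. Any value can be overridden for reduced-scale
#' runs (the defaults here are desk-scale, not cohort-scale).
#'
#' @param trait `"quantitative"` or `"binary"`.
#' @param architecture `"GA1"`, `"GA2"` or `"two_causal"`.
#' @param h2 SNP heritability (GA1/GA2).
#' @param pi_causal proportion of causal variants (GA1/GA2); the causal count
#'   is `max(1, round(pi_causal * m))`.
#' @param prevalence case fraction for binary traits.
#' @param config two-causal effect configuration `"LL"`, `"LS"` or `"SS"`.
#' @param n,m cohort samples and variants.
#' @param replicates number of replicates; each uses `train_frac` of the
#'   cohort, re-sampled per replicate.
#' @param train_frac fraction of the cohort per replicate (default 0.8).
#' @param half_width region half width in variants (500 for one-causal
#'   designs, 1000 for two-causal).
#' @param maf_range,ld_rho genotype simulator settings.
#' @param seed master seed; every stage derives a named substream from it.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(trait = c("quantitative", "binary"),
                            architecture = c("GA1", "GA2", "two_causal"),
                            h2 = 0.3, pi_causal = 0.001, prevalence = NULL,
                            config = NULL, n = 20000, m = 5000,
                            replicates = 10, train_frac = 0.8,
                            half_width = NULL, maf_range = c(0.01, 0.49),
                            ld_rho = 0.9, seed = 1) {
  trait <- match.arg(trait)
  architecture <- match.arg(architecture)
  if (trait == "binary" && is.null(prevalence))
    abort("binary traits need `prevalence`")
  if (architecture == "two_causal") {
    if (is.null(config)) abort("two-causal scenarios need `config` (LL/LS/SS)")
    half_width <- half_width %||% 1000L
    m <- 2L * as.integer(half_width) + 1L
  } else {
    assert_scalar_in(h2, 0, 1, "h2")
    assert_scalar_in(pi_causal, 0, 1, "pi_causal")
    half_width <- half_width %||% 500L
  }
  structure(list(trait = trait, architecture = architecture, h2 = h2,
                 pi_causal = pi_causal, prevalence = prevalence,
                 config = config, n = as.integer(n), m = as.integer(m),
                 replicates = as.integer(replicates), train_frac = train_frac,
                 half_width = as.integer(half_width), maf_range = maf_range,
                 ld_rho = ld_rho, seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  lab <- if (x$architecture == "two_causal")
    sprintf("two-causal %s, n=%d", x$config, x$n)
  else sprintf("%s h2=%.2f pi=%.3g, n=%d m=%d", x$architecture, x$h2,
               x$pi_causal, x$n, x$m)
  cat(sprintf("<scenario_config> %s trait, %s, %d replicates, seed %d\n",
              x$trait, lab, x$replicates, x$seed))
  invisible(x)
}

#' Read / write a scenario configuration as JSON
#'
#' @param path JSON file path.
#' @param cfg a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scenario_config, vals)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Fine-mapping method specification
#'
#' @param prior `"bayesc"` or `"bayesr"`.
#' @param estimate_pi estimate the class probabilities during fitting, or keep
#'   them fixed at their initial values.
#' @param scope `"region"` (fit each fine-mapping region separately on dense
#'   LD) or `"genome"` (one banded genome-wide fit, PIPs sliced per region).
#' @param label method label in output tables (auto-generated by default).
#' @export
blr_method <- function(prior = c("bayesr", "bayesc"), estimate_pi = TRUE,
                       scope = c("region", "genome"), label = NULL) {
  prior <- match.arg(prior)
  scope <- match.arg(scope)
  label <- label %||% paste0(prior,
                             if (estimate_pi) "-estpi" else "-fixpi",
                             if (scope == "genome") "-gw" else "")
  structure(list(prior = prior, estimate_pi = estimate_pi, scope = scope,
                 label = label), class = "blr_method")
}

# row/column subsetting of the genotype container
geno_subset <- function(G, rows = NULL, cols = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (!is.null(cols)) {
    G$counts <- G$counts[, cols, drop = FALSE]
    G$freqs <- G$freqs[cols]
    G$positions <- G$positions[cols]
    G$chrom <- G$chrom[cols]
    G$ids <- G$ids[cols]
    G$a1 <- G$a1[cols]
    G$a0 <- G$a0[cols]
    G$m <- length(G$ids)
  }
  if (!is.null(rows)) {
    G$counts <- G$counts[rows, , drop = FALSE]
    G$n <- nrow(G$counts)
  }
  G
}

#' Run a full simulation scenario end to end
#'
#' simulate genotypes once per scenario; then, per replicate: subsample the
#' cohort, simulate the phenotype, run the GWAS (linear, or logistic for
#' binary traits), define fine-mapping regions around the causal variants,
#' compute LD, fit every requested method, build credible sets, and score them
#' with the confusion rules. Deterministic given `cfg$seed`: all randomness
#' flows through named substreams. A region whose sampler fails is marked
#' non-converged (a false negative) rather than aborting the scenario.
#'
#' @param cfg a [scenario_config()].
#' @param methods list of [blr_method()] specifications.
#' @param credset `"cs2"` (LD-aware multiple sets) or `"cs1"` (simple
#'   cumulative set).
#' @param coverage,r2_min,pip_floor credible-set parameters.
#' @param opts [mcmc_options()] template (per-fit seeds are derived
#'   internally).
#' @param gw_half_bandwidth half bandwidth for genome-scope methods.
#' @return tibble: one row per replicate x method with TP, FP, FN, precision,
#'   recall, f1, auc, mean_cs_size, n_regions, n_nonconverged, and the
#'   scenario label.
#' @export
run_scenario <- function(cfg, methods = list(blr_method()), credset = c("cs2", "cs1"),
                         coverage = 0.9, r2_min = 0.5, pip_floor = 0,
                         opts = mcmc_options(n_iter = 3000, n_burnin = 500),
                         gw_half_bandwidth = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  credset <- match.arg(credset)
  two_causal <- cfg$architecture == "two_causal"
  streams <- seed_streams(cfg$seed, c("genotypes", "replicates"))
  # GA1/GA2: one cohort, replicates draw train_frac of it. Two-causal: each
  # replicate is a fresh region (new genotypes, new causal pair) at full n,
  # mirroring the per-replicate random-region design.
  cohort <- if (!two_causal)
    simulate_genotypes(cfg$n, cfg$m, maf_range = cfg$maf_range,
                       ld_rho = cfg$ld_rho, seed = streams[["genotypes"]])
  rep_seeds <- seed_streams(streams[["replicates"]],
                            sprintf("rep%d", seq_len(cfg$replicates)))
  scen_label <- scenario_label(cfg)
  out <- purrr::map_dfr(seq_len(cfg$replicates), function(k) {
    rs <- seed_streams(rep_seeds[k], c("subsample", "phenotype", "mcmc", "purity"))
    G <- if (two_causal) {
      simulate_genotypes(cfg$n, cfg$m, maf_range = cfg$maf_range,
                         ld_rho = cfg$ld_rho, seed = rs[["subsample"]])
    } else {
      rows <- with_seed(rs[["subsample"]],
                        sort(sample.int(cfg$n, round(cfg$train_frac * cfg$n))))
      geno_subset(cohort, rows = rows)
    }
    sim <- switch(cfg$architecture,
      GA1 = simulate_ga1(G, m_causal = max(1L, round(cfg$pi_causal * cfg$m)),
                         h2 = cfg$h2, seed = rs[["phenotype"]]),
      GA2 = simulate_ga2(G, m_causal = max(1L, round(cfg$pi_causal * cfg$m)),
                         h2 = cfg$h2, seed = rs[["phenotype"]]),
      two_causal = simulate_two_causal(G, config = cfg$config,
                                       seed = rs[["phenotype"]]))
    if (cfg$trait == "binary") {
      sim <- dichotomize(sim, cfg$prevalence)
      # log-odds effects go onto the standardized-phenotype scale before the
      # variance-1 sufficient-statistic machinery sees them
      ss <- standardize_sumstats(gwas_logistic(G, sim$binary))
    } else {
      ss <- gwas_linear(G, sim$y)
    }
    regions <- if (cfg$architecture == "two_causal") {
      tibble(region_id = "region1", causal_index = NA_integer_,
             start_index = 1L, end_index = cfg$m, n_snps = cfg$m,
             causal_ids = list(sim$causal$id))
    } else {
      r <- regions_from_causals(sim$causal, cfg$m, half_width = cfg$half_width,
                                ids = G$ids)
      r$causal_ids <- purrr::map(r$causal_index, function(i) G$ids[i])
      r
    }
    # region LD computed once per replicate, shared across methods
    region_data <- purrr::map(seq_len(nrow(regions)), function(i) {
      idx <- seq.int(regions$start_index[i], regions$end_index[i])
      Gr <- if (length(idx) == cfg$m) G else geno_subset(G, cols = idx)
      list(idx = idx, ss = ss[idx, , drop = FALSE], B = compute_ld(Gr))
    })
    gw_fit_cache <- new.env()
    purrr::map_dfr(seq_along(methods), function(mi) {
      meth <- methods[[mi]]
      res <- score_method(meth, mi, cfg, G, ss, regions, region_data, sim,
                          credset, coverage, r2_min, pip_floor, opts,
                          rs[["mcmc"]], gw_half_bandwidth, gw_fit_cache)
      dplyr::mutate(res, scenario = scen_label, replicate = k,
                    method = meth$label, .before = 1)
    })
  })
  out
}

scenario_label <- function(cfg) {
  if (cfg$architecture == "two_causal")
    sprintf("two_causal_%s_n%d", cfg$config, cfg$n)
  else
    sprintf("%s_h2%.2g_pi%.3g_%s%s", cfg$architecture, cfg$h2, cfg$pi_causal,
            cfg$trait,
            if (cfg$trait == "binary") sprintf("_pv%.2g", cfg$prevalence) else "")
}

# fit one method on one replicate and score it
score_method <- function(meth, mi, cfg, G, ss, regions, region_data, sim,
                         credset, coverage, r2_min, pip_floor, opts, mcmc_seed,
                         gw_half_bandwidth, gw_fit_cache) {
  prior_of <- function() {
    if (meth$prior == "bayesc") bayesc_prior(estimate_pi = meth$estimate_pi)
    else bayesr_prior(estimate_pi = meth$estimate_pi)
  }
  fit_seeds <- seed_streams(mcmc_seed,
                            paste0("m", mi, "r", seq_len(nrow(regions) + 1L)))
  all_pips <- rep(0, cfg$m)
  seen <- rep(FALSE, cfg$m)
  credsets <- list()
  conv <- logical(nrow(regions))
  sizes <- integer()
  if (meth$scope == "genome") {
    key <- paste0(meth$prior, meth$estimate_pi)
    gw_fit <- gw_fit_cache[[key]]
    if (is.null(gw_fit)) {
      hb <- gw_half_bandwidth %||% min(cfg$m - 1L, 1999L)
      Bgw <- compute_ld(G, half_bandwidth = hb)
      gw_fit <- tryCatch(
        fit_blr_genomewide(ss, Bgw, prior_of(),
                           modifyList(opts, list(seed = fit_seeds[[nrow(regions) + 1L]])),
                           regions = regions),
        error = function(e) e)
      gw_fit_cache[[key]] <- gw_fit
    }
  }
  for (i in seq_len(nrow(regions))) {
    rd <- region_data[[i]]
    fit <- if (meth$scope == "region") {
      tryCatch(fit_blr(rd$ss, rd$B, prior_of(),
                       modifyList(opts, list(seed = fit_seeds[[i]]))),
               error = function(e) e)
    } else gw_fit
    if (inherits(fit, "error")) {
      conv[i] <- FALSE
      next
    }
    pips <- if (meth$scope == "region") fit$pip else fit$pip[rd$idx]
    conv[i] <- fit$converged
    all_pips[rd$idx] <- pmax(all_pips[rd$idx], pips)
    seen[rd$idx] <- TRUE
    cs <- if (credset == "cs2") {
      cs2(pips, rd$B, ids = rd$ss$id, coverage = coverage, r2_min = r2_min,
          pip_floor = pip_floor)
    } else {
      one <- cs1(pips, ids = rd$ss$id, coverage = coverage)
      if (is.null(one)) tibble(cs_id = character(), id = character(),
                               index = integer(), pip = double(),
                               cum_pip = double())
      else dplyr::mutate(one, cs_id = "cs1", .before = 1)
    }
    if (nrow(cs)) {
      cs$region_id <- regions$region_id[i]
      credsets[[length(credsets) + 1L]] <- cs
      sizes <- c(sizes, as.integer(table(cs$cs_id)))
    }
  }
  cs_all <- if (length(credsets)) dplyr::bind_rows(credsets)
            else tibble(region_id = character(), cs_id = character(),
                        id = character())
  cls <- classify_regions(regions, cs_all,
                          convergence = tibble(region_id = regions$region_id,
                                               converged = conv))
  met <- f1_score(cls$counts)
  causal_ind <- seq_len(cfg$m) %in% sim$causal$index
  auc <- if (any(causal_ind[seen]) && any(!causal_ind[seen]))
    pip_auc(all_pips[seen], causal_ind[seen]) else NA_real_
  dplyr::bind_cols(cls$counts, met,
                   tibble(auc = auc,
                          mean_cs_size = if (length(sizes)) mean(sizes) else NA_real_,
                          n_regions = nrow(regions),
                          n_nonconverged = sum(!conv)))
}
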