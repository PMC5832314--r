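#' Pipeline configuration
#'
#' One configuration object drives the full apportionment run; all
#' randomness descends from the single `seed`, split deterministically per
#' subcatchment and stage.
#'
#' @param seed root integer seed.
#' @param n_accept,gof_threshold,n_bins,max_draws Monte Carlo settings, see
#'   [mc_config()].
#' @param ga_repeats GA restarts for [select_ga_dfa()] (default 200).
#' @param p_entry stepwise entry threshold for the GA-DFA (default 0.05).
#' @param kw_alpha Kruskal-Wallis significance threshold (default 0.05).
#' @param n_components PCA components (default 2).
#' @param min_signature_size minimum size for grown signatures (default 3).
#' @param literal_eq3 use the literal printed objective form, see
#'   [mixing_objective()].
#' @param perturb_sediment perturb sediment medians in the Monte Carlo
#'   stage (default TRUE).
#' @param signature_override optional [composite_signature()] (or list of
#'   them): skip the selection stage and apportion with these signatures.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_accept = 5000L, gof_threshold = 0.85,
                            n_bins = 100L, max_draws = 100L * n_accept,
                            ga_repeats = 200L, p_entry = 0.05,
                            kw_alpha = 0.05, n_components = 2L,
                            min_signature_size = 3L, literal_eq3 = FALSE,
                            perturb_sediment = TRUE,
                            signature_override = NULL) {
  structure(list(seed = as.integer(seed), n_accept = as.integer(n_accept),
                 gof_threshold = gof_threshold, n_bins = as.integer(n_bins),
                 max_draws = as.integer(max_draws),
                 ga_repeats = as.integer(ga_repeats), p_entry = p_entry,
                 kw_alpha = kw_alpha, n_components = as.integer(n_components),
                 min_signature_size = as.integer(min_signature_size),
                 literal_eq3 = literal_eq3,
                 perturb_sediment = perturb_sediment,
                 signature_override = signature_override),
            class = "pipeline_config")
}

# Deterministic sub-seed (< 2^31) from the root seed and stage labels.
derive_seed <- function(root, ...) {
  h <- as.numeric(root) %% 2147483647
  for (lab in as.character(c(...))) {
    for (code in utf8ToInt(lab)) h <- (h * 48271 + code) %% 2147483647
  }
  as.integer(max(1, h))
}

# Cheap reproducible fingerprint of a config for run logs.
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "signature_override")]),
             collapse = "")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         " (check that stage's inputs and configuration)", call. = FALSE)
  })
}

#' End-to-end source apportionment
#'
#' Runs, per subcatchment: replicate averaging, the bracket screening of
#' candidate tracers, selection of five composite signatures (three GA-DFA
#' plus KW-H plus PCA), Qn-scaled Monte Carlo apportionment per signature,
#' and the GOF-and-discriminatory-power weighted combination across
#' signatures; then the unweighted catchment-wide average across
#' subcatchments.
#'
#' @param sources `sample_table` of source samples (may span several
#'   subcatchments).
#' @param sediments `sample_table` of sediment samples.
#' @param panel the [tracer_panel()].
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return an `apportionment_run` list: per-subcatchment results
#'   (`range_report`, `signatures`, `mc`, `combined`), a tidy
#'   `combined_table` data.frame, and the `catchment_pct` averages.
#' @export
run_apportionment <- function(sources, sediments, panel,
                              config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("apportionment run: config ", config_hash(config),
      ", seed ", config$seed)
  subcatchments <- unique(sediments$subcatchment)
  out <- list()
  for (sc in subcatchments) {
    src <- sources[sources$subcatchment == sc, , drop = FALSE]
    sed <- sediments[sediments$subcatchment == sc, , drop = FALSE]
    attr(src, "tracers") <- tracer_names(sources)
    attr(sed, "tracers") <- tracer_names(sediments)
    if (nrow(src) == 0L) {
      stop("stage 'screen' failed: no source samples for subcatchment '",
           sc, "'", call. = FALSE)
    }
    src <- with_stage("replicate averaging", average_replicates(src))
    sed <- with_stage("replicate averaging", average_replicates(sed))
    report <- with_stage("bracket test", bracket_test(src, sed, panel))
    cand <- passing_tracers(report)
    if (length(cand) == 0L) {
      stop("stage 'bracket test' failed: no tracer passes in '", sc,
           "'; sources may not bracket the sediment", call. = FALSE)
    }
    sigs <- if (!is.null(config$signature_override)) {
      so <- config$signature_override
      if (inherits(so, "composite_signature")) list(so) else so
    } else {
      ga <- with_stage("GA-DFA selection", select_ga_dfa(
        src, cand, n_repeats = config$ga_repeats, p_entry = config$p_entry,
        seed = derive_seed(config$seed, sc, "ga")))
      kw <- with_stage("KW-H selection", select_kw_h(
        src, cand, alpha = config$kw_alpha,
        min_size = config$min_signature_size))
      pc <- with_stage("PCA selection", select_pca(
        src, cand, n_components = config$n_components,
        min_size = config$min_signature_size))
      c(ga, list(kw, pc))
    }
    src_sum <- lapply(split(as.data.frame(src), src$category), function(d) {
      attr(d, "tracers") <- tracer_names(src)
      class(d) <- class(src)
      summarize_group(d)
    })
    src_sum <- src_sum[intersect(SOURCE_CATEGORIES, names(src_sum))]
    sed_sum <- summarize_group(sed)
    mc <- lapply(seq_along(sigs), function(k) {
      cfg <- mc_config(n_accept = config$n_accept,
                       gof_threshold = config$gof_threshold,
                       n_bins = config$n_bins,
                       max_draws = config$max_draws,
                       seed = derive_seed(config$seed, sc, "mc", k))
      res <- with_stage("monte carlo", suppressWarnings(run_monte_carlo(
        sigs[[k]], src_sum, sed_sum, cfg,
        literal_eq3 = config$literal_eq3,
        perturb_sediment = config$perturb_sediment)))
      say(sprintf("  %s / %s (%s): accepted %d of %d draws, mean GOF %.3f",
                  sc, sigs[[k]]$method, paste(sigs[[k]]$tracers, collapse = "+"),
                  nrow(res$accepted), res$n_draws_used, res$mean_gof))
      res
    })
    combined <- combine_signatures(mc)
    out[[sc]] <- list(range_report = report, signatures = sigs, mc = mc,
                      combined = combined)
  }
  combined_list <- lapply(out, `[[`, "combined")
  tab <- do.call(rbind, lapply(names(out), function(sc) {
    data.frame(subcatchment = sc, category = names(combined_list[[sc]]),
               proportion = as.numeric(combined_list[[sc]]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(subcatchments = out,
                 combined_table = tab,
                 catchment_pct = catchment_summary(combined_list),
                 config = config),
            class = "apportionment_run")
}

#' Batch SOD computation
#'
#' Runs the SOD chain on every sample flask in a list of oxygen series,
#' blank-correcting each with the blank flask of the same site (or the
#' single blank if only one exists), and aggregates flask SOD values to
#' site means.
#'
#' @param series named list of [oxygen_series()] (samples and blanks).
#' @param sites optional named character vector mapping flask ids to site
#'   labels; defaults to the flask id up to the first underscore.
#' @return a `sod_run` list: `flasks` (per-flask data.frame with soc5,
#'   soc20, sod5, sod20), `sites` (site means), `results` (raw
#'   `sod_result` objects).
#' @export
run_sod <- function(series, sites = NULL) {
  is_blank <- vapply(series, function(s) s$is_blank, logical(1))
  samples <- series[!is_blank]
  blanks <- series[is_blank]
  if (length(samples) == 0L) stop("run_sod: no sample flasks", call. = FALSE)
  ids <- vapply(samples, function(s) s$flask_id, character(1))
  if (is.null(sites)) {
    sites <- stats::setNames(sub("_.*$", "", ids), ids)
  }
  blank_sites <- vapply(blanks, function(s) sub("_.*$", "", s$flask_id),
                        character(1))
  results <- lapply(samples, function(s) {
    b <- if (length(blanks) == 1L) {
      blanks[[1]]
    } else {
      hit <- which(blank_sites == sub("_.*$", "", s$flask_id))
      if (length(hit) == 0L) {
        stop("run_sod: no blank flask for site of '", s$flask_id, "'",
             call. = FALSE)
      }
      blanks[[hit[1]]]
    }
    compute_sod(s, b)
  })
  flasks <- data.frame(
    flask_id = ids,
    site = unname(sites[ids]),
    soc5 = vapply(results, `[[`, numeric(1), "soc5"),
    soc20 = vapply(results, `[[`, numeric(1), "soc20"),
    sod5 = vapply(results, `[[`, numeric(1), "sod5"),
    sod20 = vapply(results, `[[`, numeric(1), "sod20"),
    row.names = NULL, stringsAsFactors = FALSE)
  site_means <- do.call(rbind, lapply(split(flasks, flasks$site), function(d) {
    data.frame(site = d$site[1], sod5 = mean(d$sod5), sod20 = mean(d$sod20),
               n_flasks = nrow(d), row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(site_means) <- NULL
  structure(list(flasks = flasks, sites = site_means, results = results),
            class = "sod_run")
}
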