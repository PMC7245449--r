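# End-to-end orchestration: z-scores -> survey estimates -> count panels
# -> Moran screen -> space-time fits -> WHO target report. Every stage
# consumes and produces files, so runs are resumable and two runs with
# the same seeds are byte-identical.

#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the single structured configuration
#' driving [run_pipeline()]. District and wave indices are 1-based
#' throughout; the default wave-to-year map is the panel's
#' (1 = 2008, 2 = 2010/11, 3 = 2012, 4 = 2014/15, 5 = 2017).
#'
#' @param records,reference,edges Input CSV paths (child records,
#'   LMS reference, adjacency edge list).
#' @param outdir Output directory.
#' @param seed Master integer seed.
#' @param haz_limit,weight_limit Implausibility limits for
#'   [flag_implausible()].
#' @param mcmc List of [mcmc_config()] overrides.
#' @param moran_n_perm Permutations for the Moran screen.
#' @param baseline_wave,interim_wave Waves for the target assessment.
#' @param stunting_fraction Interim stunting-reduction fraction.
#' @param wasting_threshold Wasting target threshold.
#' @param wave_years Wave-to-year labels.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(records, reference, edges, outdir,
                            seed = 1, haz_limit = 6, weight_limit = 5,
                            mcmc = list(), moran_n_perm = 999,
                            baseline_wave = 3, interim_wave = 5,
                            stunting_fraction = 0.17,
                            wasting_threshold = 0.05,
                            wave_years = c("2008", "2010/11", "2012",
                                           "2014/15", "2017")) {
  structure(list(records = records, reference = reference, edges = edges,
                 outdir = outdir, seed = seed, haz_limit = haz_limit,
                 weight_limit = weight_limit, mcmc = mcmc,
                 moran_n_perm = moran_n_perm,
                 baseline_wave = baseline_wave, interim_wave = interim_wave,
                 stunting_fraction = stunting_fraction,
                 wasting_threshold = wasting_threshold,
                 wave_years = wave_years),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields above.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Generate a complete synthetic input bundle
#'
#' Writes the four input files the pipeline reads -- child records, LMS
#' reference, adjacency edge list -- from the synthetic generators, so
#' fixtures and real inputs are interchangeable. Truths are returned
#' (and saved as CSV) for recovery checks.
#'
#' @param dir Output directory for the input files.
#' @param seed Integer seed.
#' @param I Number of districts.
#' @param per_wave_sizes Children per wave.
#' @param ... Passed to [simulate_children()].
#' @return List with the file `paths`, the `truths`, and the `graph`.
#' @export
pipeline_simulate <- function(dir, seed = 1, I = 52,
                              per_wave_sizes = c(3254, 3543, 3842, 4495,
                                                 4710), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  graph <- make_district_graph(I, "grid")
  J <- length(per_wave_sizes)
  # national trajectories emulate the published per-wave national
  # prevalences of the study period (stunting 11.0% -> 7.6% with a
  # wave-2 spike, thinness/wasting 5.2% -> 3.8%, obesity 14.5% ->
  # 12.9%); for other wave counts, a linear logit drift between the
  # published endpoints
  traj <- list(stunting = c(0.110, 0.160, 0.130, 0.080, 0.076),
               thinness = c(0.052, 0.050, 0.060, 0.040, 0.038),
               obesity = c(0.145, 0.210, 0.190, 0.140, 0.129))
  mk_truth <- function(k, offset) {
    p <- traj[[k]]
    lg <- if (J == length(p)) qlogis(p) else
      seq(qlogis(p[1]), qlogis(p[length(p)]), length.out = J)
    simulate_truth(graph, J, alpha = mean(lg),
                   gamma_trend = lg - mean(lg), seed = seed + offset)
  }
  truths <- list(stunting = mk_truth("stunting", 11),
                 thinness = mk_truth("thinness", 12),
                 obesity = mk_truth("obesity", 13))
  reference <- make_reference_fixture()
  records <- simulate_children(truths, per_wave_sizes, reference,
                               seed = seed + 20, ...)
  paths <- list(records = file.path(dir, "children.csv"),
                reference = file.path(dir, "reference.csv"),
                edges = file.path(dir, "edges.csv"))
  write_children_csv(records, paths$records)
  write_reference_csv(reference, paths$reference)
  write_edges_csv(graph, paths$edges)
  truth_tbl <- dplyr::bind_rows(lapply(names(truths), function(k) {
    tr <- truths[[k]]
    tibble::tibble(outcome = k,
                   district_id = rep(seq_len(I), times = J),
                   wave = rep(seq_len(J), each = I),
                   pi_true = as.vector(tr$pi))
  }))
  readr::write_csv(truth_tbl, file.path(dir, "truth.csv"))
  list(paths = paths, truths = truths, graph = graph)
}

pipeline_stage <- function(name, outdir, expr) {
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    writeLines(sprintf("FAILED at stage '%s': %s", name,
                       conditionMessage(res)),
               file.path(outdir, "FAILED"))
    abort(sprintf("Pipeline failed at stage '%s': %s", name,
                  conditionMessage(res)),
          class = "nutrimap_pipeline_error")
  }
  res
}

#' Run the full analysis pipeline
#'
#' Executes, in order: z-score computation and classification;
#' survey-weighted prevalence tables by wave/age and by district-wave;
#' covariate association tables (Rao-Scott tests and weighted two-way
#' tabulations); the Moran spatial screen; one Bayesian space-time fit
#' per outcome; and the WHO-2025 target report. Each stage writes CSVs
#' into `config$outdir` (full-precision values plus a rounded
#' presentation column) and a YAML run manifest records seeds,
#' iteration counts, acceptance rates and convergence verdicts. Any
#' stage failure aborts with the stage name; partial outputs are kept
#' alongside a `FAILED` marker.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fits, target tables and manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "FAILED"))

  inputs <- pipeline_stage("inputs", outdir, {
    for (p in c(config$records, config$reference, config$edges)) {
      if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    }
    list(records = read_children_csv(config$records),
         reference = read_reference_csv(config$reference))
  })

  z <- pipeline_stage("zscore", outdir, {
    z <- compute_zscores(inputs$records, inputs$reference)
    z <- flag_implausible(z, config$haz_limit, config$weight_limit)
    z <- classify_nutrition(z)
    readr::write_csv(
      dplyr::mutate(z, haz_rounded = round(.data$haz, 2),
                    weight_based_z_rounded = round(.data$weight_based_z, 2)),
      file.path(outdir, "zscores.csv"))
    z
  })

  outcomes <- c(stunting = "stunted", thinness = "thin_wasted",
                obesity = "obese")

  prev_wave <- pipeline_stage("prevalence", outdir, {
    z2 <- dplyr::mutate(z, age_year = pmin(floor(.data$age_months / 12), 4))
    tabs <- lapply(names(outcomes), function(k) {
      col <- outcomes[[k]]
      by_age <- weighted_prevalence(z2, !!rlang::sym(col),
                                    by = c("wave", "age_year"))
      overall <- weighted_prevalence(z2, !!rlang::sym(col), by = "wave")
      overall$age_year <- NA_integer_
      dplyr::mutate(dplyr::bind_rows(by_age, overall), outcome = k)
    })
    tab <- dplyr::bind_rows(tabs)
    readr::write_csv(dplyr::mutate(tab, p_rounded = round(.data$p_hat, 3)),
                     file.path(outdir, "prevalence_by_wave.csv"))
    tab
  })

  prev_cell <- pipeline_stage("prevalence_district", outdir, {
    tabs <- lapply(names(outcomes), function(k) {
      col <- outcomes[[k]]
      dplyr::mutate(
        weighted_prevalence(z, !!rlang::sym(col),
                            by = c("district_id", "wave")),
        outcome = k)
    })
    tab <- dplyr::bind_rows(tabs)
    readr::write_csv(dplyr::mutate(tab, p_rounded = round(.data$p_hat, 3)),
                     file.path(outdir, "prevalence_by_district_wave.csv"))
    tab
  })

  assoc <- pipeline_stage("associations", outdir, {
    covs <- intersect(c("ethnicity", "birth_weight", "income", "hunger",
                        "environment", "mother_bmi", "mother_age",
                        "mother_edu", "father_edu"), names(z))
    rows <- list()
    for (k in names(outcomes)) {
      col <- outcomes[[k]]
      zz <- z[!is.na(z[[col]]), ]
      zz$..status <- ifelse(zz[[col]], "yes", "no")
      for (cv in covs) {
        tst <- rao_scott_chi2(zz, !!rlang::sym("..status"), !!rlang::sym(cv))
        rows[[length(rows) + 1L]] <- dplyr::mutate(tst, outcome = k,
                                                   covariate = cv)
      }
    }
    tab <- dplyr::bind_rows(rows)
    readr::write_csv(dplyr::mutate(tab, p_rounded = round(.data$p_value, 4)),
                     file.path(outdir, "associations.csv"))
    tab
  })

  graph <- pipeline_stage("spatial", outdir, {
    read_edges_csv(config$edges)
  })

  panels <- pipeline_stage("panel", outdir, {
    ps <- lapply(names(outcomes), function(k) {
      pc <- prev_cell[prev_cell$outcome == k, ]
      sizes <- dplyr::rename(pc[, c("district_id", "wave", "n_valid")],
                             n = "n_valid")
      panel <- build_count_panel(pc, sizes, I = graph$n_nodes,
                                 outcome = k)
      write_panel_csv(panel, file.path(outdir, paste0("panel_", k, ".csv")))
      panel
    })
    names(ps) <- names(outcomes)
    ps
  })

  moran <- pipeline_stage("moran", outdir, {
    last <- panels[[1]]$J
    pm <- sapply(panels, function(p) {
      ifelse(p$n[, last] > 0, p$Y[, last] / pmax(p$n[, last], 1), NA)
    })
    # districts unobserved in the final wave get the national mean
    pm <- apply(pm, 2, function(v) ifelse(is.na(v), mean(v, na.rm = TRUE), v))
    tab <- moran_screen(pm, graph, n_perm = config$moran_n_perm,
                        seed = config$seed + 300)
    readr::write_csv(tab, file.path(outdir, "moran.csv"))
    tab
  })

  fits <- pipeline_stage("fit", outdir, {
    fs <- list()
    for (k in names(outcomes)) {
      cfg <- do.call(mcmc_config,
                     c(list(seed = config$seed + 400 + match(k, names(outcomes))),
                       config$mcmc))
      fit <- fit_spacetime(panels[[k]], graph, cfg)
      readr::write_csv(
        dplyr::mutate(tidy(fit), median_rounded = round(.data$median, 3)),
        file.path(outdir, paste0("posterior_", k, ".csv")))
      readr::write_csv(fit$diagnostics,
                       file.path(outdir, paste0("diagnostics_", k, ".csv")))
      fs[[k]] <- fit
    }
    fs
  })

  targets <- pipeline_stage("targets", outdir, {
    map <- c(stunting = "stunting", thinness = "wasting",
             obesity = "obesity")
    rows <- lapply(names(outcomes), function(k) {
      tab <- assess_who_targets(
        fits[[k]], map[[k]], baseline_wave = config$baseline_wave,
        interim_wave = config$interim_wave,
        fraction = config$stunting_fraction,
        threshold = config$wasting_threshold)
      nat <- tibble::tibble(district_id = NA_integer_,
                            met = NA,
                            exceedance_prob = NA_real_,
                            significant = NA,
                            count_met = attr(tab, "count"),
                            percent_met = attr(tab, "percent"))
      dplyr::mutate(dplyr::bind_rows(
        dplyr::mutate(tab, count_met = NA_integer_,
                      percent_met = NA_real_), nat), outcome = k)
    })
    tab <- dplyr::bind_rows(rows)
    readr::write_csv(tab, file.path(outdir, "targets.csv"))
    tab
  })

  manifest <- pipeline_stage("manifest", outdir, {
    m <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("nutrimap")),
      converged = lapply(fits, function(f) f$converged),
      total_iterations = lapply(fits, function(f) f$total_iter),
      acceptance_rates = lapply(fits, function(f)
        as.list(setNames(round(f$acceptance, 4),
                         c("alpha", "phi", "gamma", "nu")))),
      dic = lapply(fits, function(f) round(f$dic, 2)))
    yaml::write_yaml(m, file.path(outdir, "manifest.yaml"))
    m
  })

  invisible(list(zscores = z, prevalence = prev_wave,
                 prevalence_cells = prev_cell, associations = assoc,
                 moran = moran, panels = panels, fits = fits,
                 targets = targets, manifest = manifest))
}
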