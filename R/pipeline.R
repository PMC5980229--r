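#' Run configuration for an end-to-end pipeline run
#'
#' @param out_dir output directory for the report bundle.
#' @param seed top-level seed; child seeds for every stage are derived
#'   deterministically, so the whole bundle is reproducible.
#' @param sim a [sim_config()] to generate the cohort, or NULL to read an
#'   existing cohort from \code{data_dir}.
#' @param data_dir directory holding \code{<group>_units.csv},
#'   \code{<group>_spikes.csv}, \code{<group>_events.csv} triplets (used
#'   when \code{sim} is NULL; when \code{sim} is given the generated
#'   cohort is written here, default \code{<out_dir>/data}).
#' @param groups group names to analyse.
#' @param config a [classifier_config()].
#' @param verbose print stage progress and attrition counts.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                       data_dir = NULL,
                       groups = c("avoidance", "naive", "fear"),
                       config = classifier_config(), verbose = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 data_dir = data_dir %||% file.path(out_dir, "data"),
                 groups = groups, config = config, verbose = verbose),
            class = "run_config")
}

pipeline_stage <- function(name, expr, verbose) {
  if (verbose) message(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

write_stamped_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Proportion of inhibited units by PL subregion
#'
#' Counts inhibited versus non-inhibited units in rostral and caudal PL
#' and compares the two regions with Fisher's exact test. In the recorded
#' avoidance cohort every tone-inhibited unit sat in rPL.
#'
#' @param responses data.frame from [classify_units()].
#' @param units the corresponding list of \code{unit_recording} (for
#'   region labels).
#' @param label polarity to compare, default \code{"inhibited"}.
#' @return List: \code{table} (2 x 2 counts, rows rPL/cPL, columns
#'   label/other), \code{p} (Fisher exact), per-region proportions.
#' @export
region_breakdown <- function(responses, units, label = "inhibited") {
  region <- vapply(units, `[[`, character(1), "region")[responses$unit_id]
  is_lab <- responses$label == label
  tab <- rbind(rPL = c(sum(is_lab & region == "rPL"),
                       sum(!is_lab & region == "rPL")),
               cPL = c(sum(is_lab & region == "cPL"),
                       sum(!is_lab & region == "cPL")))
  colnames(tab) <- c(label, "other")
  ft <- fisher_exact_2x2(tab)
  list(table = tab, p = ft$p,
       prop_rPL = tab[1, 1] / sum(tab[1, ]),
       prop_cPL = tab[2, 1] / sum(tab[2, ]))
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> read -> classify (tone onset and platform entry)
#' -> ISI latencies -> behavior -> population statistics, writing a report
#' bundle of CSV/JSON files under \code{rc$out_dir}. Every output carries
#' the seed and a configuration hash in its header; the run is
#' deterministic given the seed. Any stage failure aborts with the stage
#' name and cause.
#'
#' @param rc a [run_config()].
#' @return The report, invisibly: per-group unit counts and label counts,
#'   contingency statistics (chi-square across groups for each polarity,
#'   Fisher avoidance-vs-naive, region breakdown), latency summary,
#'   behavioral aggregates, Venn overlap, \code{config_hash}.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  cfg <- rc$config
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(c(deparse(unclass(cfg)), deparse(unclass(rc$sim)),
                        sprintf("seed=%d", rc$seed)))

  if (!is.null(rc$sim)) {
    pipeline_stage("simulate", {
      sim <- rc$sim
      sim$seed <- rc$seed
      simulate_cohort(sim, out_dir = rc$data_dir)
    }, rc$verbose)
  }

  cohort <- pipeline_stage("read", {
    out <- list()
    for (g in rc$groups) {
      up <- file.path(rc$data_dir, paste0(g, "_units.csv"))
      sp <- file.path(rc$data_dir, paste0(g, "_spikes.csv"))
      ep <- file.path(rc$data_dir, paste0(g, "_events.csv"))
      out[[g]] <- list(units = read_units(up, sp),
                       session = read_events(ep))
    }
    out
  }, rc$verbose)

  responses <- pipeline_stage("classify", {
    out <- list()
    for (g in rc$groups) {
      tone <- classify_units(cohort[[g]]$units, cohort[[g]]$session,
                             "tone_onset", cfg)
      plat <- classify_units(cohort[[g]]$units, cohort[[g]]$session,
                             "platform_entry", cfg)
      both <- rbind(tone, plat)
      both$group <- g
      write_stamped_csv(both,
                        file.path(rc$out_dir,
                                  paste0(g, "_responses.csv")),
                        rc$seed, hash)
      if (rc$verbose)
        message(sprintf("  %s: %d units, tone labels: %s", g,
                        nrow(tone),
                        paste(names(table(tone$label)),
                              table(tone$label), collapse = " ")))
      out[[g]] <- list(tone = tone, platform = plat)
    }
    out
  }, rc$verbose)

  zmaps <- pipeline_stage("population_maps", {
    g <- rc$groups[1]
    zm <- build_zscore_matrix(cohort[[g]]$units, cohort[[g]]$session,
                              "tone_onset", cfg)
    props <- time_resolved_proportions(zm, cfg)
    hm <- heatmap_matrix(zm, cfg)
    write_stamped_csv(props, file.path(rc$out_dir, "tone_proportions.csv"),
                      rc$seed, hash)
    hm_df <- data.frame(unit_id = rownames(hm$z),
                        round(hm$z, 6), check.names = FALSE)
    names(hm_df)[-1] <- sprintf("bin_%03d", seq_len(ncol(hm$z)))
    write_stamped_csv(hm_df, file.path(rc$out_dir, "tone_heatmap.csv"),
                      rc$seed, hash)
    list(proportions = props)
  }, rc$verbose)

  latency <- pipeline_stage("latency", {
    g <- rc$groups[1]
    rec <- latency_records(cohort[[g]]$units, cohort[[g]]$session, cfg)
    summ <- per_cell_latency_summary(rec)
    corr <- latency_correlation(summ$summary$mean_inhibition_latency_s,
                                summ$summary$mean_platform_latency_s)
    write_stamped_csv(rec, file.path(rc$out_dir, "latency_records.csv"),
                      rc$seed, hash)
    write_stamped_csv(summ$summary,
                      file.path(rc$out_dir, "latency_summary.csv"),
                      rc$seed, hash)
    list(summary = summ, correlation = corr)
  }, rc$verbose)

  behavior <- pipeline_stage("behavior", {
    out <- list()
    for (g in rc$groups) {
      bs <- behavior_summary(cohort[[g]]$session, cfg)
      write_stamped_csv(bs, file.path(rc$out_dir,
                                      paste0(g, "_behavior.csv")),
                        rc$seed, hash)
      out[[g]] <- bs
    }
    out
  }, rc$verbose)

  statres <- pipeline_stage("stats", {
    tone_tab <- function(pol) {
      t(vapply(rc$groups, function(g) {
        lab <- responses[[g]]$tone$label
        c(sum(lab == pol), sum(lab != pol & lab != "unclassifiable"))
      }, numeric(2)))
    }
    res <- list()
    for (pol in c("excited", "inhibited")) {
      tab <- tone_tab(pol)
      colnames(tab) <- c(pol, "other")
      res[[paste0("chi_square_", pol)]] <-
        c(chi_square(tab), list(counts = tab))
      if (all(c("avoidance", "naive") %in% rc$groups))
        res[[paste0("fisher_av_naive_", pol)]] <-
          fisher_exact_2x2(tab[c("avoidance", "naive"), ])
    }
    g <- rc$groups[1]
    res$region <- region_breakdown(responses[[g]]$tone, cohort[[g]]$units)
    res$venn <- overlap_venn(responses[[g]]$tone, responses[[g]]$platform)
    res
  }, rc$verbose)

  report <- pipeline_stage("report", {
    label_counts <- lapply(rc$groups, function(g)
      as.list(table(responses[[g]]$tone$label)))
    names(label_counts) <- rc$groups
    rep <- list(
      seed = rc$seed, config_hash = hash,
      n_units = vapply(cohort, function(x) length(x$units), numeric(1)),
      tone_label_counts = label_counts,
      chi_square = list(
        excited = statres$chi_square_excited[c("statistic", "df", "p")],
        inhibited = statres$chi_square_inhibited[c("statistic", "df", "p")]),
      region = list(p = statres$region$p,
                    prop_rPL = statres$region$prop_rPL,
                    prop_cPL = statres$region$prop_cPL),
      venn = statres$venn,
      latency_correlation = latency$correlation,
      behavior_means = lapply(behavior, function(b)
        list(pct_platform = mean(b$pct_platform),
             pct_freezing = mean(b$pct_freezing),
             suppression = mean(b$suppression),
             median_avoid_latency_s = stats::median(b$avoid_latency_s))))
    jsonlite::write_json(rep, file.path(rc$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  }, rc$verbose)

  invisible(list(report = report, responses = responses,
                 latency = latency, behavior = behavior,
                 stats = statres, proportions = zmaps$proportions))
}
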