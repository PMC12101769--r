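#' Per-participant response metrics from trace tables
#'
#' Applies [extract_metrics()] to every contributing participant column of
#' a [trace_table].
#'
#' @param tab A [trace_table].
#' @param config An [analysis_config].
#' @return Data frame: `participant` plus the four metric columns.
#' @export
table_metrics <- function(tab, config = analysis_config()) {
  stopifnot(inherits(tab, "trace_table"))
  rows <- lapply(tab$contributors, function(id) {
    tr <- trace_from_table(tab, id, config$pulse_duration)
    m <- extract_metrics(tr, pulse_duration = config$pulse_duration,
                         t_post_offset = config$pipr_t_post_offset)
    data.frame(participant = id,
               a = m$time_to_max_constriction_ms,
               b = m$diameter_at_max_constriction_pct,
               c = m$redilation_rate_pct_s,
               d = m$diameter_6s_post_offset_pct)
  })
  do.call(rbind, rows)
}

#' Full two-group analysis of a set of trace tables
#'
#' Runs the complete statistical chain on per-participant pupil traces:
#'
#' * per-participant extraction of the four response parameters for each
#'   available stimulus;
#' * between-group Welch t-tests on every parameter, with Bonferroni
#'   correction within each stimulus's family of four comparisons;
#' * paired t-tests of each parameter between the melanopsin- and
#'   LMS-directed stimuli (participants contributing both);
#' * PIPR (red minus blue) per participant at 6 s post offset and at the
#'   timepoint of maximal control-minus-glaucoma group difference, with
#'   Welch comparisons of both;
#' * ROC/AUC (DeLong 95% CI) for every parameter and both PIPR read-outs;
#' * optional Spearman correlations of each glaucoma-group parameter with
#'   clinical covariates.
#'
#' @param tables Named list of [trace_table] objects; recognized names are
#'   `{group}_{stimulus}` for group in `glaucoma`/`control` and stimulus in
#'   `melanopsin`, `lms`, `red`, `blue`. Missing stimuli yield a partial
#'   bundle with a warning.
#' @param clinical Optional data frame with columns `participant`,
#'   `vf_md_db`, `vf_psd_db`, `cprnfl_um` (glaucoma group used).
#' @param config An [analysis_config].
#' @return List of class `analysis_bundle` with elements `metrics`
#'   (long data frame), `group_tests`, `paired_tests`, `pipr`, `roc`,
#'   `correlations` (NULL without clinical data), `config`.
#' @export
run_full_analysis <- function(tables, clinical = NULL,
                              config = analysis_config()) {
  stim_sets <- list(melanopsin = c("glaucoma_melanopsin",
                                   "control_melanopsin"),
                    lms = c("glaucoma_lms", "control_lms"),
                    red = c("glaucoma_red", "control_red"),
                    blue = c("glaucoma_blue", "control_blue"))
  have <- vapply(stim_sets, function(k) all(k %in% names(tables)),
                 logical(1))
  if (!any(have)) stop("no complete stimulus table pair supplied")
  for (s in names(stim_sets)[!have])
    warning("stimulus '", s, "' missing; partial bundle", call. = FALSE)

  metrics <- list(); group_tests <- list(); roc <- list()
  for (s in c("melanopsin", "lms")) {
    if (!have[[s]]) next
    mg <- table_metrics(tables[[paste0("glaucoma_", s)]], config)
    mc <- table_metrics(tables[[paste0("control_", s)]], config)
    mg$group <- "glaucoma"; mc$group <- "control"
    mg$stimulus <- s; mc$stimulus <- s
    metrics[[s]] <- rbind(mg, mc)
    pvals <- numeric(4); names(pvals) <- c("a", "b", "c", "d")
    for (par in c("a", "b", "c", "d")) {
      gt <- welch_t(mg[[par]], mc[[par]])
      pvals[par] <- gt$p
      group_tests[[paste(s, par, sep = "_")]] <- gt
      roc[[paste(s, par, sep = "_")]] <-
        roc_auc(c(mg[[par]], mc[[par]]),
                c(rep(1, nrow(mg)), rep(0, nrow(mc))))
    }
    attr(group_tests, paste0(s, "_bonferroni")) <-
      bonferroni(pvals, family_size = config$bonferroni_family)
  }

  paired_tests <- NULL
  if (have[["melanopsin"]] && have[["lms"]]) {
    paired_tests <- list()
    mel <- do.call(rbind, metrics["melanopsin"])
    lms <- do.call(rbind, metrics["lms"])
    common <- intersect(mel$participant, lms$participant)
    mel <- mel[match(common, mel$participant), ]
    lms <- lms[match(common, lms$participant), ]
    for (par in c("a", "b", "c", "d"))
      paired_tests[[par]] <- paired_t(mel[[par]], lms[[par]])
  }

  pipr <- NULL
  if (have[["red"]] && have[["blue"]]) {
    pipr <- pipr_analysis(tables, config)
    roc[["pipr_6s"]] <- roc_auc(pipr$per_participant$pipr_6s,
                                pipr$per_participant$group == "glaucoma")
    roc[["pipr_maxdiff"]] <- roc_auc(
      pipr$per_participant$pipr_maxdiff,
      pipr$per_participant$group == "glaucoma")
  }

  correlations <- NULL
  if (!is.null(clinical) && length(metrics) > 0) {
    correlations <- list()
    allm <- do.call(rbind, metrics)
    gl <- allm[allm$group == "glaucoma", ]
    cl <- clinical[match(gl$participant, clinical$participant), ]
    for (s in unique(gl$stimulus)) for (par in c("a", "b", "c", "d"))
      for (cov in c("vf_md_db", "vf_psd_db", "cprnfl_um")) {
        sel <- gl$stimulus == s
        ok <- is.finite(gl[[par]][sel]) & is.finite(cl[[cov]][sel])
        if (sum(ok) >= 4)
          correlations[[paste(s, par, cov, sep = "_")]] <-
            spearman(gl[[par]][sel][ok], cl[[cov]][sel][ok])
      }
  }

  structure(list(metrics = do.call(rbind, metrics),
                 group_tests = group_tests, paired_tests = paired_tests,
                 pipr = pipr, roc = roc, correlations = correlations,
                 config = config),
            class = "analysis_bundle")
}

# PIPR per participant at 6 s post offset and at the timepoint of maximal
# control-minus-glaucoma mean PIPR difference.
pipr_analysis <- function(tables, config) {
  pd <- config$pulse_duration
  per_group <- function(grp) {
    red <- tables[[paste0(grp, "_red")]]
    blue <- tables[[paste0(grp, "_blue")]]
    ids <- intersect(red$contributors, blue$contributors)
    rows <- lapply(ids, function(id) {
      r <- trace_from_table(red, id, pd)
      b <- trace_from_table(blue, id, pd)
      data.frame(participant = id, group = grp,
                 pipr_6s = compute_pipr(r, b,
                                        t_post_offset =
                                          config$pipr_t_post_offset,
                                        pulse_duration = pd))
    })
    do.call(rbind, rows)
  }
  per <- rbind(per_group("glaucoma"), per_group("control"))

  # group-mean PIPR curves on the common grid
  pipr_curve <- function(grp) {
    red <- tables[[paste0(grp, "_red")]]
    blue <- tables[[paste0(grp, "_blue")]]
    ids <- intersect(red$contributors, blue$contributors)
    traces <- lapply(ids, function(id) {
      r <- trace_from_table(red, id, pd)
      b <- trace_from_table(blue, id, pd)
      list(time = r$time, pupil = r$pupil - b$pupil)
    })
    group_curve(traces, label = grp)
  }
  ctrl <- pipr_curve("control"); glau <- pipr_curve("glaucoma")
  t_max <- max_group_difference_time(ctrl, glau,
                                     window = config$pipr_search_window,
                                     pulse_duration = pd)
  at <- pd + t_max
  add_maxdiff <- function(grp) {
    red <- tables[[paste0(grp, "_red")]]
    blue <- tables[[paste0(grp, "_blue")]]
    vapply(per$participant[per$group == grp], function(id) {
      r <- trace_from_table(red, id, pd)
      b <- trace_from_table(blue, id, pd)
      compute_pipr(r, b, t_post_offset = t_max, pulse_duration = pd)
    }, numeric(1))
  }
  per$pipr_maxdiff <- NA_real_
  per$pipr_maxdiff[per$group == "glaucoma"] <- add_maxdiff("glaucoma")
  per$pipr_maxdiff[per$group == "control"] <- add_maxdiff("control")

  list(per_participant = per,
       t_max_difference_post_offset = t_max,
       test_6s = welch_t(per$pipr_6s[per$group == "glaucoma"],
                         per$pipr_6s[per$group == "control"]),
       test_maxdiff = welch_t(per$pipr_maxdiff[per$group == "glaucoma"],
                              per$pipr_maxdiff[per$group == "control"]),
       control_curve = ctrl, glaucoma_curve = glau)
}

#' Reproduce the full supplementary-data analysis
#'
#' Loads the eight per-participant trace tables
#' (`{control,glaucoma}{Blue,Red,LMS,Melanopsin}Stimulus.csv`) and, if
#' present, the mean stimulus radiance table (`S9 Mean Stimulus
#' Radiances`-style CSV) from a directory, then runs [run_full_analysis()]
#' and the Table-1-style contrast/luminance computation.
#'
#' @param dir Directory holding the CSVs.
#' @param radiance_file Optional radiance CSV name (searched in `dir`).
#' @param config An [analysis_config].
#' @return List: `analysis` ([run_full_analysis()] bundle) and `contrasts`
#'   (per-pair contrast/luminance summary, NULL without a radiance file).
#' @export
reproduce_supplementary <- function(dir,
                                    radiance_file = "S9MeanStimulusRadiances.csv",
                                    config = analysis_config()) {
  stim_file <- function(grp, stim)
    file.path(dir, sprintf("%s%sStimulus.csv", grp, stim))
  wanted <- expand.grid(grp = c("control", "glaucoma"),
                        stim = c("Blue", "Red", "LMS", "Melanopsin"),
                        stringsAsFactors = FALSE)
  paths <- mapply(stim_file, wanted$grp, wanted$stim)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("missing supplementary trace files:\n  ",
         paste(basename(missing), collapse = "\n  "))
  key <- function(grp, stim)
    paste(grp, c(Blue = "blue", Red = "red", LMS = "lms",
                 Melanopsin = "melanopsin")[[stim]], sep = "_")
  tables <- stats::setNames(
    lapply(seq_len(nrow(wanted)), function(i) read_trace_table(paths[i])),
    mapply(key, wanted$grp, wanted$stim))
  contrasts <- NULL
  rad_path <- file.path(dir, radiance_file)
  if (file.exists(rad_path)) {
    spectra <- read_radiance_table(rad_path)
    contrasts <- list(
      melanopsin_pair = stimulus_contrasts(
        list(background = spectra$MelBg, pulse = spectra$MelPulse)),
      lms_pair = stimulus_contrasts(
        list(background = spectra$LMSBg, pulse = spectra$LMSPulse)),
      luminance = c(
        mel_pulse = luminance(spectra$MelPulse),
        mel_background = luminance(spectra$MelBg),
        lms_pulse = luminance(spectra$LMSPulse),
        lms_background = luminance(spectra$LMSBg),
        red = luminance(spectra$red),
        blue = luminance(spectra$blue)))
  }
  list(analysis = run_full_analysis(tables, config = config),
       contrasts = contrasts)
}
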