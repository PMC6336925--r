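#' Run the full factorial filter sweep
#'
#' For every filter specification, amplitude preset, filtered-signal domain
#' and serial-correlation treatment: (optionally motion-correct the OD
#' data,) filter in the stated domain, convert to concentration if the
#' filter ran on OD, fit the GLM per channel and chromophore, take subject
#' medians over channels, and compute the group statistics against the
#' reference beta. IIR cells whose realized coefficients are unstable are
#' recorded as skipped, mirroring the dashed cells of the study tables.
#'
#' @param dataset output of [assemble_dataset()]
#' @param grid list of [filter_spec()] (default [default_filter_grid()])
#' @param corrections subset of `c("none", "downsample", "precolor")`
#' @param domains subset of `c("conc", "OD")`
#' @param protocol,hrf the protocol and HRF used to build the data
#' @param mbll an [mbll_params()] (needed for the OD domain)
#' @param motion_correct run tPCA motion correction on OD before filtering
#' @param motion a [motion_params()]
#' @param verbose print one status line per cell
#' @return a `sweep_table`: `records` data frame plus a list of
#'   `group_result` objects keyed by record id
#' @export
run_sweep <- function(dataset, grid = default_filter_grid(),
                      corrections = "precolor", domains = "conc",
                      protocol = protocol_spec(), hrf = hrf_spec(),
                      mbll = mbll_params(), motion_correct = FALSE,
                      motion = motion_params(), verbose = FALSE) {
  records <- list()
  results <- list()
  for (si in seq_along(grid)) {
    spec <- grid[[si]]
    id <- spec_id(spec)
    coeffs <- design_filter(spec)
    stab <- check_stability(coeffs)
    if (!stab$is_stable) {
      for (amp_label in names(dataset)) for (dom in domains)
        for (corr in corrections) for (chrom in c("HbO2", "HbR")) {
          records[[length(records) + 1L]] <- data.frame(
            amplitude = amp_label, spec = id, domain = dom,
            correction = corr, chromophore = chrom,
            status = "skipped_unstable", mean_beta = NA, bias = NA,
            t_stat = NA, t_p = NA, df = NA, shapiro_w = NA, shapiro_p = NA,
            n_outliers = NA)
        }
      if (verbose) message(id, ": skipped (unstable)")
      next
    }
    for (amp_label in names(dataset)) {
      recs <- dataset[[amp_label]]
      ref <- attr(recs, "reference") %||% NULL
      for (dom in domains) {
        betas <- sweep_betas(recs, coeffs, dom, corrections, protocol, hrf,
                             mbll, motion_correct, motion)
        for (corr in corrections) for (chrom in c("HbO2", "HbR")) {
          med <- betas[[corr]][[chrom]]
          reference <- reference_beta(dataset, amp_label, chrom)
          gr <- group_result(med, reference)
          key <- paste(amp_label, id, dom, corr, chrom, sep = "|")
          results[[key]] <- gr
          records[[length(records) + 1L]] <- data.frame(
            amplitude = amp_label, spec = id, domain = dom,
            correction = corr, chromophore = chrom, status = "ok",
            mean_beta = gr$mean_beta, bias = gr$bias, t_stat = gr$t_stat,
            t_p = gr$t_p, df = gr$df, shapiro_w = gr$shapiro_w,
            shapiro_p = gr$shapiro_p, n_outliers = sum(gr$outlier_flags))
        }
        if (verbose) message(id, " ", amp_label, " ", dom, ": done")
      }
    }
  }
  structure(list(records = do.call(rbind, records), results = results,
                 grid = grid),
            class = "sweep_table")
}

# per-subject median betas for one (filter, domain) cell, all corrections
sweep_betas <- function(recs, coeffs, domain, corrections, protocol, hrf,
                        mbll, motion_correct, motion) {
  out <- lapply(corrections, function(z)
    list(HbO2 = numeric(0), HbR = numeric(0)))
  names(out) <- corrections
  for (rec in recs) {
    ch_betas <- lapply(corrections, function(z)
      list(HbO2 = numeric(0), HbR = numeric(0)))
    names(ch_betas) <- corrections
    for (ch in rec$channels) {
      pair <- ch
      if (domain == "OD") {
        od <- od_from_conc(pair, mbll)
        if (motion_correct) {
          od <- tpca_correct(od, params = motion)$channels
        }
        od <- lapply(od, function(s) apply_filter(coeffs, s))
        pair <- conc_from_od(od, mbll)
      } else {
        pair <- list(hbo2 = apply_filter(coeffs, pair$hbo2),
                     hbr = apply_filter(coeffs, pair$hbr))
      }
      for (corr in corrections) {
        ch_betas[[corr]]$HbO2 <- c(
          ch_betas[[corr]]$HbO2,
          fit_glm_corrected(pair$hbo2, protocol, hrf, corr)$beta_task)
        ch_betas[[corr]]$HbR <- c(
          ch_betas[[corr]]$HbR,
          fit_glm_corrected(pair$hbr, protocol, hrf, corr)$beta_task)
      }
    }
    for (corr in corrections) {
      out[[corr]]$HbO2 <- c(out[[corr]]$HbO2,
                            subject_median(ch_betas[[corr]]$HbO2,
                                           rec$excluded_channels))
      out[[corr]]$HbR <- c(out[[corr]]$HbR,
                           subject_median(ch_betas[[corr]]$HbR,
                                          rec$excluded_channels))
    }
  }
  out
}

# reference beta for an amplitude label, from the preset table
reference_beta <- function(dataset, amp_label, chromophore) {
  presets <- amplitude_presets()
  amp <- presets[[amp_label]]
  if (is.null(amp))
    stop("unknown amplitude label (custom labels need explicit references): ",
         amp_label)
  if (chromophore == "HbO2") amp$hbo2_amp else amp$hbr_amp
}

#' Rank filter specifications by beta recovery
#'
#' Aggregates the chosen criterion over all rows of each spec present in
#' the (possibly pre-filtered) records — restrict the table first to rank
#' within a family or amplitude. Criteria: `abs_t` (smallest mean |t|,
#' the default), `p_near_alpha` (smallest mean |p - 0.05|, the study's
#' stated heuristic), `abs_bias` (smallest mean |group bias|). Ties break
#' deterministically by lower order, then narrower pass band.
#'
#' @param table a `sweep_table` or its `records` data frame
#' @param criterion ranking criterion
#' @param grid the filter grid (for tie-break metadata); taken from the
#'   sweep table when available
#' @return data frame of specs ordered best first, with the aggregated score
#' @export
rank_filters <- function(table, criterion = c("abs_t", "p_near_alpha",
                                              "abs_bias"),
                         grid = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(table, "sweep_table")) {
    if (is.null(grid)) grid <- table$grid
    table <- table$records
  }
  tab <- table[table$status == "ok", , drop = FALSE]
  if (!nrow(tab)) stop("no successful records to rank")
  score <- switch(criterion,
    abs_t = abs(tab$t_stat),
    p_near_alpha = abs(tab$t_p - 0.05),
    abs_bias = abs(tab$bias))
  agg <- stats::aggregate(score, by = list(spec = tab$spec), FUN = mean)
  names(agg)[2] <- "score"
  ord_of <- function(id) {
    if (!is.null(grid) && !is.null(grid[[id]])) grid[[id]]$order
    else suppressWarnings(as.integer(sub(".*_o(\\d+)_.*", "\\1", id)))
  }
  band_of <- function(id) {
    if (!is.null(grid) && !is.null(grid[[id]])) {
      s <- grid[[id]]
      s$fc_high - (s$fc_low %||% 0)
    } else NA_real_
  }
  agg$order <- vapply(agg$spec, ord_of, numeric(1))
  agg$bandwidth <- vapply(agg$spec, band_of, numeric(1))
  agg[order(agg$score, agg$order, agg$bandwidth, agg$spec), , drop = FALSE]
}

#' Group-statistic table in the study layout
#'
#' Rows = filter order, columns = cut-off set, for one (amplitude, domain,
#' correction, chromophore, family, characteristic) slice; unstable cells
#' are dashes.
#'
#' @param table a `sweep_table`
#' @param amplitude,domain,correction,chromophore,family,characteristic
#'   slice selectors
#' @param statistic records column to tabulate (e.g. `"t_stat"`,
#'   `"shapiro_w"`, `"mean_beta"`)
#' @return data frame, orders x cut-offs
#' @export
export_group_table <- function(table, amplitude = "Amplitude1",
                               domain = "conc", correction = "precolor",
                               chromophore = "HbO2", family = "FIR",
                               characteristic = "BP",
                               statistic = "t_stat") {
  stopifnot(inherits(table, "sweep_table"))
  rec <- table$records
  grid <- table$grid
  keep <- vapply(rec$spec, function(id) {
    s <- grid[[id]]
    !is.null(s) && s$family == family && s$characteristic == characteristic
  }, logical(1))
  rec <- rec[keep & rec$amplitude == amplitude & rec$domain == domain &
               rec$correction == correction &
               rec$chromophore == chromophore, , drop = FALSE]
  if (!nrow(rec)) stop("no records match the requested slice")
  orders <- sort(unique(vapply(rec$spec, function(id) grid[[id]]$order,
                               numeric(1))))
  fcs <- sort(unique(vapply(rec$spec, function(id) grid[[id]]$fc_high,
                            numeric(1))))
  out <- matrix("-", length(orders), length(fcs),
                dimnames = list(orders, paste0("fc_", fcs)))
  for (i in seq_len(nrow(rec))) {
    s <- grid[[rec$spec[i]]]
    if (rec$status[i] == "ok")
      out[as.character(s$order), paste0("fc_", s$fc_high)] <-
        formatC(rec[[statistic]][i], format = "g", digits = 3)
  }
  as.data.frame(out)
}

#' Read a sweep configuration file (YAML or JSON)
#'
#' Keys mirror the constructor arguments: `protocol` (n_blocks, task_dur,
#' rest_dur, lead_in), `hrf` (peak_time, undershoot_time, undershoot_ratio,
#' kernel_duration), `noise` (drift_amp_uM, drift_timescale, white_sd_uM,
#' hbr_scale, components), `amplitudes` (list of hbo2_uM / hbr_uM / label),
#' `fs`, `n_subjects`, `n_channels`, and a mandatory `master_seed`.
#' Concentrations are given in micromolar and converted at this boundary.
#'
#' @param path configuration file path
#' @return list of constructed spec objects ready for
#'   [assemble_dataset()] / [run_sweep()]
#' @export
read_sweep_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$master_seed)) stop("config must set master_seed")
  pr <- cfg$protocol %||% list()
  protocol <- protocol_spec(pr$n_blocks %||% 14, pr$task_dur %||% 20,
                            pr$rest_dur %||% 20, pr$lead_in %||% 20)
  hh <- cfg$hrf %||% list()
  hrf <- hrf_spec(hh$peak_time %||% 6, hh$undershoot_time %||% 16,
                  hh$undershoot_ratio %||% (1 / 6),
                  hh$kernel_duration %||% 32)
  nn <- cfg$noise %||% list()
  comp <- if (!is.null(nn$components)) {
    as.data.frame(lapply(as.data.frame(nn$components), unlist))
  } else default_noise_components()
  noise <- noise_spec(components = comp,
                      drift_amp = uMol(nn$drift_amp_uM %||% 1.0),
                      drift_timescale = nn$drift_timescale %||% 200,
                      white_sd = uMol(nn$white_sd_uM %||% 0.05),
                      hbr_scale = nn$hbr_scale %||% (1 / 3))
  amps <- if (!is.null(cfg$amplitudes)) {
    lapply(cfg$amplitudes, function(a)
      amplitude_spec(uMol(a$hbo2_uM), uMol(a$hbr_uM), a$label))
  } else amplitude_presets()
  list(protocol = protocol, hrf = hrf, noise = noise, amplitudes = amps,
       fs = cfg$fs %||% 5, n_subjects = cfg$n_subjects %||% 18,
       n_channels = cfg$n_channels %||% 16,
       master_seed = cfg$master_seed)
}
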