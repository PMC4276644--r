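# Measurement-driven input adjustments: model-vs-measured traffic
# comparison, VMT-conserving AADT rescaling, diesel-fraction
# reclassification and cohort relabeling.

new_adjustment_log <- function(links = NULL, receptors = NULL, scenario = "") {
  structure(list(
    links = if (is.null(links)) tibble::tibble(
      link_id = character(), field = character(), old = character(),
      new = character(), reason = character()) else links,
    receptors = if (is.null(receptors)) tibble::tibble(
      receptor_id = character(), old_label = character(),
      new_label = character(), reason = character()) else receptors,
    scenario = scenario
  ), class = "adjustment_log")
}

#' @export
print.adjustment_log <- function(x, ...) {
  cat(sprintf("<adjustment_log> %s: %d link change(s), %d receptor change(s)\n",
              x$scenario, nrow(x$links), nrow(x$receptors)))
  invisible(x)
}

#' Write an adjustment log (CSV pair + human-readable report)
#'
#' @param log an `adjustment_log`.
#' @param stem path stem; writes `<stem>_links.csv`, `<stem>_receptors.csv`
#'   and `<stem>_report.txt`.
#' @export
write_adjustment_log <- function(log, stem) {
  readr::write_csv(log$links, paste0(stem, "_links.csv"), progress = FALSE)
  readr::write_csv(log$receptors, paste0(stem, "_receptors.csv"), progress = FALSE)
  rep <- c(sprintf("Adjustment scenario: %s", log$scenario),
           sprintf("Link changes: %d", nrow(log$links)),
           sprintf("  %s %s: %s -> %s (%s)", log$links$link_id, log$links$field,
                   log$links$old, log$links$new, log$links$reason),
           sprintf("Receptor changes: %d", nrow(log$receptors)),
           sprintf("  %s: %s -> %s (%s)", log$receptors$receptor_id,
                   log$receptors$old_label, log$receptors$new_label,
                   log$receptors$reason))
  writeLines(rep, paste0(stem, "_report.txt"))
  invisible(stem)
}

#' Compare modelled and measured AADT
#'
#' Percent difference `100 * (model - measured) / measured` per link and
#' measurement year.
#'
#' @param links a `road_links` object (model AADT).
#' @param ptr a `ptr_records` object; link_ids must resolve in `links`.
#' @return Tibble: link_id, year, model_aadt, measured_aadt, pct_diff.
#' @export
compare_aadt <- function(links, ptr) {
  idx <- match(ptr$link_id, links$id)
  if (anyNA(idx)) {
    stop("compare_aadt: PTR link id(s) not in network: ",
         paste(unique(ptr$link_id[is.na(idx)]), collapse = ", "))
  }
  if (any(ptr$measured_aadt == 0)) stop("compare_aadt: measured AADT of zero")
  tibble::tibble(
    link_id = ptr$link_id, year = ptr$year,
    model_aadt = links$aadt[idx], measured_aadt = ptr$measured_aadt,
    pct_diff = 100 * (links$aadt[idx] - ptr$measured_aadt) / ptr$measured_aadt)
}

#' VMT-conserving interstate AADT rescale
#'
#' Multiplies the AADT of every interstate (NFC 11) link by
#' `interstate_factor` and redistributes the removed vehicle-miles
#' travelled onto the freeway (NFC 12) links as a uniform AADT increment
#' (removed VMT divided by total freeway length), so network VMT
#' (`sum AADT * length`) is conserved exactly.
#'
#' @param links a `road_links` object.
#' @param interstate_factor multiplier on interstate AADT (default 0.8,
#'   a 20% reduction).
#' @return List: `links` (adjusted `road_links`) and `log`
#'   (an `adjustment_log`).
#' @export
rescale_aadt <- function(links, interstate_factor = 0.8) {
  out <- links
  log <- new_adjustment_log(scenario = sprintf("interstate AADT x %.3g, VMT conserved",
                                               interstate_factor))
  if (interstate_factor == 1) return(list(links = out, log = log))
  ii <- which(out$nfc == 11L)
  ff <- which(out$nfc == 12L)
  if (length(ii) && !length(ff)) {
    stop("rescale_aadt: no NFC 12 links to absorb the removed VMT")
  }
  removed_vmt <- sum((1 - interstate_factor) * out$aadt[ii] * out$length[ii])
  inc <- removed_vmt / sum(out$length[ff])
  old_i <- out$aadt[ii]; old_f <- out$aadt[ff]
  out$aadt[ii] <- out$aadt[ii] * interstate_factor
  out$aadt[ff] <- out$aadt[ff] + inc
  log$links <- dplyr::bind_rows(
    tibble::tibble(link_id = as.character(out$id[ii]), field = "aadt",
                   old = format(old_i), new = format(out$aadt[ii]),
                   reason = sprintf("interstate AADT scaled by %.3g (measured overestimate)",
                                    interstate_factor)),
    tibble::tibble(link_id = as.character(out$id[ff]), field = "aadt",
                   old = format(old_f), new = format(out$aadt[ff]),
                   reason = sprintf("+%.4g veh/day to conserve network VMT", inc)))
  list(links = out, log = log)
}

#' Network vehicle-miles travelled
#' @param links a `road_links` object.
#' @return `sum(AADT * length)` in vehicle-metres/day.
#' @export
network_vmt <- function(links) sum(links$aadt * links$length)

#' Reassign link fleet mixes from measured diesel shares
#'
#' For links with a commercial-AADT measurement, the measured diesel share
#' (`CAADT / AADT`, commercial volume as a diesel proxy) selects the
#' catalog fleet mix whose diesel percentage is nearest; ties keep the
#' original mix. The link's HD/LD diesel group follows the new mix
#' (diesel percentage of the interstate mix and above = HD). AADT is never
#' touched. Links without a CAADT measurement are unchanged.
#'
#' @param links a `road_links` object.
#' @param ptr a `ptr_records` object.
#' @param mixes named list of `fleet_mix` objects (the catalog).
#' @param year use records from this year only; default all years.
#' @return List: `links` (adjusted) and `log` (an `adjustment_log`).
#' @export
reassign_diesel <- function(links, ptr, mixes = urban_fleet_mixes(), year = NULL) {
  p <- tibble::as_tibble(ptr)
  if (!is.null(year)) p <- p[p$year == year, ]
  p <- p[!is.na(p$measured_caadt), ]
  out <- links
  log <- new_adjustment_log(scenario = "fleet mix from measured CAADT/AADT diesel share")
  if (!nrow(p)) return(list(links = out, log = log))
  if (any(p$measured_caadt > p$measured_aadt)) {
    stop("reassign_diesel: CAADT exceeds AADT")
  }
  df_cat <- vapply(mixes, diesel_fraction, numeric(1))
  hd_cut <- if ("interstate" %in% names(mixes)) df_cat[["interstate"]] else max(df_cat)
  rows <- list()
  for (k in seq_len(nrow(p))) {
    i <- match(p$link_id[k], out$id)
    if (is.na(i)) stop("reassign_diesel: PTR link id not in network: ", p$link_id[k])
    share <- 100 * p$measured_caadt[k] / p$measured_aadt[k]
    dist <- abs(df_cat - share)
    best <- names(mixes)[dist == min(dist)]
    new_mix <- if (out$mix_name[i] %in% best) out$mix_name[i] else best[1]
    if (!identical(new_mix, out$mix_name[i])) {
      old_mix <- out$mix_name[i]
      out$mix_name[i] <- new_mix
      old_grp <- out$diesel_group[i]
      if (!is.na(old_grp)) {
        out$diesel_group[i] <- if (df_cat[[new_mix]] >= hd_cut) "HD" else "LD"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        link_id = as.character(out$id[i]), field = "mix_name",
        old = old_mix, new = new_mix,
        reason = sprintf("measured diesel share %.2f%% nearest %s mix (%.2f%%)",
                         share, new_mix, df_cat[[new_mix]]))
    }
  }
  if (length(rows)) log$links <- dplyr::bind_rows(rows)
  list(links = out, log = log)
}

#' Relabel receptor cohorts after link adjustments
#'
#' Reruns [classify_receptors()] on the adjusted links. Receptors whose
#' label moves from HTHD to HTLD keep the dedicated "HD to LD" label so the
#' reclassified group remains visible in reporting.
#'
#' @param recs receptors carrying their pre-adjustment labels (classified).
#' @param adjusted_links the adjusted `road_links`.
#' @param ... passed to [classify_receptors()].
#' @return List: `receptors` (relabelled) and `log` (an `adjustment_log`).
#' @export
relabel_cohorts <- function(recs, adjusted_links, ...) {
  old <- recs$group_label
  new_recs <- classify_receptors(recs, adjusted_links, ...)
  moved <- old == "HTHD" & new_recs$group_label == "HTLD"
  new_recs$group_label[moved] <- "HD to LD"
  changed <- which(new_recs$group_label != old)
  log <- new_adjustment_log(scenario = "cohort relabeling after link adjustments")
  if (length(changed)) {
    log$receptors <- tibble::tibble(
      receptor_id = as.character(new_recs$id[changed]),
      old_label = old[changed], new_label = new_recs$group_label[changed],
      reason = "nearest high-traffic roadway group changed")
  }
  list(receptors = receptors(new_recs), log = log)
}
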