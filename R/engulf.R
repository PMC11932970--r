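#' Lysosomal compartment inside microglia
#'
#' Voxelwise intersection of the CD68 (lysosome) mask with the Iba1
#' (microglia) mask. CD68 signal outside microglia is discarded; the result
#' is the phagocytic compartment against which engulfment is scored.
#'
#' @param iba1_mask,cd68_mask [binary_mask()]s of identical shape and voxel
#'   size.
#' @return A [binary_mask()] labelled `"cd68_in_iba1"`.
#' @export
lysosome_in_microglia <- function(iba1_mask, cd68_mask) {
  stopifnot(inherits(iba1_mask, "binary_mask"), inherits(cd68_mask, "binary_mask"))
  if (!identical(dim(iba1_mask$grid), dim(cd68_mask$grid))) {
    stop("mask shapes differ", call. = FALSE)
  }
  if (!isTRUE(all.equal(unlist(iba1_mask$voxel), unlist(cd68_mask$voxel)))) {
    stop("mask voxel sizes differ", call. = FALSE)
  }
  binary_mask(iba1_mask$grid & cd68_mask$grid, iba1_mask$voxel,
              source_channel = "cd68_in_iba1")
}

#' Per-section engulfment readouts
#'
#' Computes the assay's core quantities from three co-registered binary
#' masks: microglial (Iba1) volume, lysosomal volume within microglia
#' (CD68 AND Iba1), total marker volume, engulfed marker volume
#' (marker AND CD68 AND Iba1) and the percentage of marker engulfed
#' (100 x engulfed / marker). A secondary contact volume (marker AND Iba1,
#' irrespective of lysosomal localisation) is also reported, since microglial
#' contact without lysosomal engulfment is biologically distinct.
#'
#' When the section contains no marker signal the percentage is undefined:
#' `percent_engulfed` is `NA` and `percent_defined` is `FALSE`, but all
#' volumes are still reported.
#'
#' @param iba1_mask,cd68_mask,marker_mask [binary_mask()]s of identical shape
#'   and voxel size.
#' @param marker_kind Marker label, one of `"VGAT"`, `"VGLUT2"`, `"AFIBRE"`,
#'   `"CASPASE3"` (free text allowed).
#' @param animal_id,section_id Identifiers carried into the result row.
#' @return A one-row data.frame of class `engulfment_result` with columns
#'   `animal_id`, `section_id`, `marker_kind`, `iba1_volume_um3`,
#'   `cd68_in_iba1_volume_um3`, `marker_volume_um3`, `engulfed_volume_um3`,
#'   `contact_volume_um3`, `percent_engulfed`, `percent_defined`.
#' @export
engulfment_metrics <- function(iba1_mask, cd68_mask, marker_mask,
                               marker_kind = "VGAT",
                               animal_id = NA_character_,
                               section_id = NA_integer_) {
  for (m in list(iba1_mask, cd68_mask, marker_mask)) {
    stopifnot(inherits(m, "binary_mask"))
  }
  if (!identical(dim(iba1_mask$grid), dim(cd68_mask$grid)) ||
      !identical(dim(iba1_mask$grid), dim(marker_mask$grid))) {
    stop("mask shapes differ", call. = FALSE)
  }
  vv <- voxel_volume(iba1_mask$voxel)
  iba1 <- iba1_mask$grid
  lyso <- iba1 & cd68_mask$grid
  marker <- marker_mask$grid
  iba1_v <- sum(iba1) * vv
  lyso_v <- sum(lyso) * vv
  marker_v <- sum(marker) * vv
  engulfed_v <- sum(marker & lyso) * vv
  contact_v <- sum(marker & iba1) * vv
  defined <- marker_v > 0
  pct <- if (defined) 100 * engulfed_v / marker_v else NA_real_
  out <- data.frame(
    animal_id = as.character(animal_id),
    section_id = section_id,
    marker_kind = as.character(marker_kind),
    iba1_volume_um3 = iba1_v,
    cd68_in_iba1_volume_um3 = lyso_v,
    marker_volume_um3 = marker_v,
    engulfed_volume_um3 = engulfed_v,
    contact_volume_um3 = contact_v,
    percent_engulfed = pct,
    percent_defined = defined,
    stringsAsFactors = FALSE)
  class(out) <- c("engulfment_result", class(out))
  out
}

normalize_incision <- function(x) {
  if (is.logical(x)) return(ifelse(x, "+", "-"))
  x <- as.character(x)
  if (!all(x %in% c("-", "+"))) {
    stop("incision flags must be '-'/'+' or logical", call. = FALSE)
  }
  x
}

#' Group label in IN(neonatal, adult) notation
#'
#' @param neonatal,adult Incision flags (`"-"`/`"+"` or logical).
#' @return Character vector like `"IN(-,+)"`.
#' @export
in_group_label <- function(neonatal, adult) {
  sprintf("IN(%s,%s)", normalize_incision(neonatal), normalize_incision(adult))
}

#' Aggregate per-section results to a per-animal cohort table
#'
#' Animals -- not sections -- are the experimental unit of the assay, so each
#' animal's sections are averaged (arithmetic mean) before any statistics.
#' Animals with fewer than `min_sections` sections (default 6) are excluded
#' with a warning; sections with an undefined engulfment percentage are
#' dropped from the percentage mean only.
#'
#' @param results A data.frame of stacked [engulfment_metrics()] rows.
#' @param manifest A data.frame with one row per animal: `animal_id`, `sex`
#'   (`"F"`/`"M"`), `neonatal_incision` and `adult_incision` (`"-"`/`"+"` or
#'   logical). Every animal in `results` must appear here.
#' @param min_sections Minimum sections per animal (default 6).
#' @return A data.frame of class `cohort_table`: one row per animal with its
#'   factors, `group` (IN notation), `n_sections` and the per-animal mean of
#'   every volumetric and percentage readout.
#' @export
aggregate_cohort <- function(results, manifest, min_sections = 6) {
  results <- as.data.frame(results)
  manifest <- as.data.frame(manifest)
  need <- c("animal_id", "sex", "neonatal_incision", "adult_incision")
  if (!all(need %in% names(manifest))) {
    stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  manifest <- manifest[!duplicated(manifest$animal_id), , drop = FALSE]
  missing <- setdiff(unique(results$animal_id), manifest$animal_id)
  if (length(missing)) {
    stop(sprintf("animals present in results but absent from manifest: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  metric_cols <- intersect(
    c("iba1_volume_um3", "cd68_in_iba1_volume_um3", "marker_volume_um3",
      "engulfed_volume_um3", "contact_volume_um3", "percent_engulfed"),
    names(results))
  ids <- unique(results$animal_id)
  rows <- lapply(ids, function(a) {
    sub <- results[results$animal_id == a, , drop = FALSE]
    mrow <- manifest[manifest$animal_id == a, , drop = FALSE]
    means <- vapply(metric_cols, function(cl) mean(sub[[cl]], na.rm = TRUE),
                    numeric(1))
    cbind(
      data.frame(animal_id = a,
                 sex = as.character(mrow$sex),
                 neonatal_incision = normalize_incision(mrow$neonatal_incision),
                 adult_incision = normalize_incision(mrow$adult_incision),
                 n_sections = nrow(sub),
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(means)))
  })
  tab <- do.call(rbind, rows)
  tab$group <- in_group_label(tab$neonatal_incision, tab$adult_incision)
  low <- tab$n_sections < min_sections
  if (any(low)) {
    warning(sprintf("excluding %d animal(s) below the %d-section minimum: %s",
                    sum(low), min_sections,
                    paste(tab$animal_id[low], collapse = ", ")), call. = FALSE)
    tab <- tab[!low, , drop = FALSE]
  }
  rownames(tab) <- NULL
  class(tab) <- c("cohort_table", class(tab))
  tab
}
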