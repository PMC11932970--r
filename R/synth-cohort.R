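#' Factorial cohort design for the synthetic generator
#'
#' Describes a full factorial cohort over sex and neonatal/adult incision
#' with per-group additive mean shifts on the engulfed fraction, the puncta
#' density and the cell size, hierarchical variability (between-animal and
#' within-animal, both as coefficients of variation), and one master seed.
#' Dropping a factor level (e.g. `adult_levels = "-"`) collapses the design
#' to a smaller factorial.
#'
#' @param n_per_group Animals per factor-level combination (>= 2).
#' @param sections_per_animal Sections imaged per animal (default 6, the
#'   usual per-animal replication of the assay).
#' @param base Named list of baseline values: `engulfed_fraction`,
#'   `puncta_density` (per 1000 um^3), `cell_scale` (multiplier on soma and
#'   branch radii).
#' @param effects Named list of additive shifts, each a vector with entries
#'   `sex` (added for males), `neonatal` and `adult` (added for `"+"`), for
#'   `engulfed_fraction`, `puncta_density` and `cell_scale`.
#' @param between_animal_cv Between-animal coefficient of variation of each
#'   latent per-animal value.
#' @param within_animal_cv Within-animal (section-to-section) coefficient of
#'   variation.
#' @param sexes,neonatal_levels,adult_levels Factor levels included.
#' @param age_class `"adult"` or `"neonate"`; drives the z-crop rule at
#'   analysis time.
#' @param shape,voxel,cell_params,puncta_params,optics Imaging and structure
#'   parameters passed to [make_section()]. The puncta density and engulfed
#'   fraction inside `puncta_params` are overridden per section by the
#'   cohort hierarchy (`base` + effects + animal + section draws); only its
#'   `radius_um` is taken from here.
#' @param marker_kind Marker label.
#' @param seed Master seed; all per-animal / per-section randomness is
#'   derived from it via [split_seed()].
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 4,
                          sections_per_animal = 6,
                          base = list(engulfed_fraction = 0.04,
                                      puncta_density = 40,
                                      cell_scale = 1),
                          effects = list(
                            engulfed_fraction = c(sex = 0, neonatal = 0, adult = 0),
                            puncta_density = c(sex = 0, neonatal = 0, adult = 0),
                            cell_scale = c(sex = 0, neonatal = 0, adult = 0)),
                          between_animal_cv = 0.2,
                          within_animal_cv = 0.1,
                          sexes = c("F", "M"),
                          neonatal_levels = c("-", "+"),
                          adult_levels = c("-", "+"),
                          age_class = "adult",
                          shape = c(24, 128, 128),
                          voxel = voxel_preset_20x(),
                          cell_params = cell_model_params(),
                          puncta_params = puncta_field_params(),
                          optics = optics_params(),
                          marker_kind = "VGAT",
                          seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (between_animal_cv < 0 || within_animal_cv < 0) {
    stop("coefficients of variation must be non-negative", call. = FALSE)
  }
  for (nm in c("engulfed_fraction", "puncta_density", "cell_scale")) {
    if (is.null(effects[[nm]])) effects[[nm]] <- c(sex = 0, neonatal = 0, adult = 0)
    effects[[nm]] <- effects[[nm]][c("sex", "neonatal", "adult")]
    effects[[nm]][is.na(effects[[nm]])] <- 0
    names(effects[[nm]]) <- c("sex", "neonatal", "adult")
  }
  structure(list(
    n_per_group = n_per_group, sections_per_animal = sections_per_animal,
    base = base, effects = effects,
    between_animal_cv = between_animal_cv, within_animal_cv = within_animal_cv,
    sexes = sexes, neonatal_levels = neonatal_levels,
    adult_levels = adult_levels, age_class = age_class,
    shape = shape, voxel = as_voxel_size(voxel),
    cell_params = cell_params, puncta_params = puncta_params, optics = optics,
    marker_kind = marker_kind, seed = as.integer(seed)),
    class = "cohort_design")
}

group_mean <- function(base, eff, sex, neo, adult) {
  base + (sex == "M") * eff[["sex"]] + (neo == "+") * eff[["neonatal"]] +
    (adult == "+") * eff[["adult"]]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a full factorial cohort with known ground truth
#'
#' Draws a latent truth hierarchy -- group mean, between-animal effect,
#' within-animal section jitter -- for the engulfed fraction, puncta density
#' and cell scale, then (optionally) renders every section through
#' [make_section()]. Latent fractions are clipped to `[0, 1]` (flagged in the
#' truth table). Deterministic given the design's master seed; per-animal and
#' per-section sub-seeds come from [split_seed()] so the cohort can be
#' extended without disturbing earlier draws.
#'
#' With `render = "none"` no stacks are built, but each section still
#' realizes its Poisson puncta count and binomial engulfed count, so the
#' per-section `realized_fraction` carries the counting noise the imaging
#' path would see. This is the fast ground-truth pathway used for power
#' simulations.
#'
#' @param design A [cohort_design()].
#' @param render `"full"` (stacks + truth masks) or `"none"` (truth only).
#' @param section_fn Optional function applied to each fully rendered section
#'   record as soon as it is built; its return value replaces the record's
#'   `stack`/`truth` payload (stored as `result`), so large cohorts can be
#'   processed without holding every stack in memory.
#' @return A list with `sections` (list of records: `animal_id`,
#'   `section_index`, `marker_kind`, latent/realized truth, and for full
#'   rendering `stack` + `truth`), `truth_table` (one row per animal:
#'   factors, latent means, realized mean fraction), and `manifest`
#'   (per-animal factor table for [aggregate_cohort()]).
#' @export
make_cohort <- function(design, render = c("full", "none"), section_fn = NULL) {
  render <- match.arg(render)
  d <- design
  stopifnot(inherits(d, "cohort_design"))
  groups <- expand.grid(sex = d$sexes, neonatal = d$neonatal_levels,
                        adult = d$adult_levels, stringsAsFactors = FALSE)
  sections <- list()
  truth_rows <- list()
  a_idx <- 0L
  for (g in seq_len(nrow(groups))) {
    gr <- groups[g, ]
    mu_f <- group_mean(d$base$engulfed_fraction, d$effects$engulfed_fraction,
                       gr$sex, gr$neonatal, gr$adult)
    mu_d <- group_mean(d$base$puncta_density, d$effects$puncta_density,
                       gr$sex, gr$neonatal, gr$adult)
    mu_c <- group_mean(d$base$cell_scale, d$effects$cell_scale,
                       gr$sex, gr$neonatal, gr$adult)
    for (a in seq_len(d$n_per_group)) {
      a_idx <- a_idx + 1L
      animal_id <- sprintf("A%03d", a_idx)
      a_seed <- split_seed(d$seed, a_idx)
      av <- with_seed(a_seed, {
        c(f = mu_f + stats::rnorm(1, 0, d$between_animal_cv * abs(mu_f)),
          dens = mu_d + stats::rnorm(1, 0, d$between_animal_cv * abs(mu_d)),
          cs = mu_c + stats::rnorm(1, 0, d$between_animal_cv * abs(mu_c)))
      })
      animal_f <- clip01(av[["f"]])
      clipped <- animal_f != av[["f"]]
      animal_dens <- max(av[["dens"]], 0)
      animal_cs <- max(av[["cs"]], 0.2)
      sec_real <- numeric(d$sections_per_animal)
      for (s in seq_len(d$sections_per_animal)) {
        s_seed <- split_seed(d$seed, a_idx, s)
        sv <- with_seed(split_seed(s_seed, 7), {
          c(f = animal_f + stats::rnorm(1, 0, d$within_animal_cv * animal_f),
            dens = animal_dens + stats::rnorm(1, 0, d$within_animal_cv * animal_dens))
        })
        sec_f <- clip01(sv[["f"]])
        sec_dens <- max(sv[["dens"]], 0)
        pp <- puncta_field_params(
          density_per_1000um3 = sec_dens,
          radius_um = d$puncta_params$radius_um,
          engulfed_fraction = sec_f)
        cp <- d$cell_params
        cp$soma_radius_um <- cp$soma_radius_um * animal_cs
        cp$branch_radius_um <- cp$branch_radius_um * animal_cs
        rec <- list(animal_id = animal_id, section_index = s,
                    sex = gr$sex, neonatal_incision = gr$neonatal,
                    adult_incision = gr$adult, age_class = d$age_class,
                    marker_kind = d$marker_kind,
                    latent_fraction = sec_f, latent_density = sec_dens,
                    seed = s_seed, clipped = clipped)
        if (render == "full") {
          sec <- make_section(cp, pp, d$optics, d$voxel, d$shape,
                              seed = s_seed, marker_kind = d$marker_kind)
          rec$stack <- sec$stack
          rec$truth <- sec$truth
          sec_real[s] <- sec$truth$true_engulfed_fraction
        } else {
          sec_real[s] <- with_seed(s_seed, {
            v_total <- prod(d$shape) * voxel_volume(d$voxel)
            n <- stats::rpois(1, sec_dens * v_total / 1000)
            if (n > 0) stats::rbinom(1, n, sec_f) / n else NA_real_
          })
        }
        rec$realized_fraction <- sec_real[s]
        if (!is.null(section_fn) && render == "full") {
          rec$result <- section_fn(rec)
          rec$stack <- NULL
          rec$truth <- NULL
        }
        sections[[length(sections) + 1L]] <- rec
      }
      truth_rows[[a_idx]] <- data.frame(
        animal_id = animal_id, sex = gr$sex,
        neonatal_incision = gr$neonatal, adult_incision = gr$adult,
        group = in_group_label(gr$neonatal, gr$adult),
        group_mean_fraction = mu_f,
        true_engulfed_fraction = animal_f,
        true_puncta_density = animal_dens,
        true_cell_scale = animal_cs,
        realized_mean_fraction = mean(sec_real, na.rm = TRUE),
        clipped = clipped,
        stringsAsFactors = FALSE)
    }
  }
  truth_table <- do.call(rbind, truth_rows)
  manifest <- truth_table[, c("animal_id", "sex", "neonatal_incision",
                              "adult_incision")]
  manifest$age_class <- d$age_class
  list(sections = sections, truth_table = truth_table, manifest = manifest)
}

#' Default apoptotic hotspot mixture
#'
#' Three regions of elevated apoptotic density on the unit hemisection
#' template (medio-lateral coordinate `u` in `[0,1]` from the midline,
#' dorso-ventral `v` in `[0,1]` from the dorsal surface): superficial lateral
#' dorsal horn, the region around the central canal, and the ventral horn.
#'
#' @return A data.frame with columns `u`, `v`, `weight`, `sigma`.
#' @export
default_hotspots <- function() {
  data.frame(u = c(0.55, 0.10, 0.35),
             v = c(0.12, 0.50, 0.85),
             weight = c(1, 1, 1),
             sigma = c(0.07, 0.07, 0.09))
}

# Inside test for the unit hemisection template: half-ellipse with the flat
# (midline) edge at u = 0.
in_hemisection <- function(u, v) {
  u >= 0 & u <= 1 & v >= 0 & v <= 1 & (u^2 + (2 * v - 1)^2) <= 1
}

sample_hotspot_points <- function(n, hotspots) {
  if (n == 0) {
    return(data.frame(u = numeric(), v = numeric()))
  }
  w <- hotspots$weight / sum(hotspots$weight)
  u <- numeric(n); v <- numeric(n)
  got <- 0L
  while (got < n) {
    k <- sample.int(nrow(hotspots), n - got, replace = TRUE, prob = w)
    uu <- stats::rnorm(length(k), hotspots$u[k], hotspots$sigma[k])
    vv <- stats::rnorm(length(k), hotspots$v[k], hotspots$sigma[k])
    ok <- in_hemisection(uu, vv)
    n_ok <- sum(ok)
    if (n_ok > 0) {
      u[(got + 1):(got + n_ok)] <- uu[ok]
      v[(got + 1):(got + n_ok)] <- vv[ok]
      got <- got + n_ok
    }
  }
  data.frame(u = u, v = v)
}

#' Generate synthetic apoptosis-counting sections
#'
#' Per-section apoptotic-cell counts are Poisson with a control or incision
#' rate; cell locations are drawn from a mixture of Gaussian hotspots on the
#' unit hemisection template. With `render = TRUE` each section's caspase-3
#' channel is rendered (spherical blobs through the optics model); with
#' `render = FALSE` only the ground-truth centroids are returned.
#' Deterministic given `seed`.
#'
#' @param rate_control,rate_incision Mean apoptotic cells per section in the
#'   two groups. Defaults (0.30 and 0.53) put the group difference at the
#'   scale typically reported for neonatal-incision cohorts.
#' @param n_animals Animals per group.
#' @param sections Sections per animal.
#' @param hotspots Hotspot mixture (see [default_hotspots()]).
#' @param seed Master seed.
#' @param shape,voxel,optics Rendering geometry.
#' @param blob_radius_um Rendered cell-body radius (um).
#' @param render Render caspase channels, or truth only.
#' @return A list with `sections` (records: `animal_id`, `section_index`,
#'   `group`, `truth` data.frame of centroids with `z, y, x, u, v`, and
#'   optionally `stack`) and `manifest`.
#' @export
make_apoptosis_sections <- function(rate_control = 0.30, rate_incision = 0.53,
                                    n_animals = 8, sections = 8,
                                    hotspots = default_hotspots(),
                                    seed = 1,
                                    shape = c(8, 128, 128),
                                    voxel = voxel_preset_20x(),
                                    optics = optics_params(),
                                    blob_radius_um = 2.5,
                                    render = TRUE) {
  stopifnot(rate_control >= 0, rate_incision >= 0, n_animals >= 1, sections >= 1)
  voxel <- as_voxel_size(voxel)
  dm <- as.integer(shape)
  out <- list()
  manifest <- list()
  a_idx <- 0L
  for (grp in c("control", "incision")) {
    rate <- if (grp == "control") rate_control else rate_incision
    for (a in seq_len(n_animals)) {
      a_idx <- a_idx + 1L
      animal_id <- sprintf("AP%03d", a_idx)
      manifest[[a_idx]] <- data.frame(
        animal_id = animal_id, group = grp,
        neonatal_incision = if (grp == "incision") "+" else "-",
        stringsAsFactors = FALSE)
      for (s in seq_len(sections)) {
        s_seed <- split_seed(seed, 1000L + a_idx, s)
        rec <- with_seed(s_seed, {
          n <- stats::rpois(1, rate)
          pts <- sample_hotspot_points(n, hotspots)
          # map template (u,v) to voxel coordinates
          x <- 1 + pts$u * (dm[3] - 1)
          y <- 1 + pts$v * (dm[2] - 1)
          z <- if (n > 0) 1 + stats::runif(n) * (dm[1] - 1) else numeric()
          truth <- data.frame(z = z, y = y, x = x, u = pts$u, v = pts$v)
          rec <- list(animal_id = animal_id, section_index = s, group = grp,
                      truth = truth, seed = s_seed)
          if (render) {
            mask <- stamp_balls(dm, cbind(round(z), round(y), round(x)),
                                ball_offsets(blob_radius_um, voxel))
            img <- render_channel(mask, optics, voxel)
            rec$stack <- channel_stack(array(img, c(1, dm)), voxel, "caspase3",
                                       provenance = sprintf("synthetic apoptosis seed=%d", s_seed))
          }
          rec
        })
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  list(sections = out, manifest = do.call(rbind, manifest))
}
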