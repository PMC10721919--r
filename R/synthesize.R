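# Synthetic tongue surfaces: a gently undulating base sheet bearing sparse
# large dome-shaped fungiform papillae and numerous small crown-shaped
# filiform papillae, with measurement noise and participant-level shape
# effects. Ground-truth annotations ride along with every surface.

papilla_defaults <- list(
  fungiform = list(base_radius = 439, height = 250, spike_count = 0L),
  filiform  = list(base_radius = 177.5, height = 170, spike_count = 6L)
)

#' Specification of a single planted papilla
#'
#' @param type `"fungiform"` (dome) or `"filiform"` (crown).
#' @param center length-2 xy base position (um).
#' @param base_radius base-disk radius (um); defaults: fungiform 439
#'   (diameter ~878 um), filiform 177.5 (diameter ~355 um).
#' @param height apex height above the local base surface (um).
#' @param sharpness dimensionless > 0; scales profile exponents so larger
#'   values give higher peak curvature.
#' @param spike_count number of crown sub-spikes (filiform only; fungiform
#'   must have 0).
#' @return A list of class `papilla_spec`.
#' @export
papilla_spec <- function(type = c("fungiform", "filiform"), center = c(0, 0),
                         base_radius = NULL, height = NULL, sharpness = 1,
                         spike_count = NULL) {
  type <- match.arg(type)
  def <- papilla_defaults[[type]]
  base_radius <- base_radius %||% def$base_radius
  height <- height %||% def$height
  spike_count <- as.integer(spike_count %||% def$spike_count)
  stopifnot(base_radius > 0, height > 0, sharpness > 0, spike_count >= 0)
  if (type == "fungiform" && spike_count != 0L) {
    stop("fungiform papillae have spike_count = 0")
  }
  structure(list(type = type, center = as.numeric(center[1:2]),
                 base_radius = base_radius, height = height,
                 sharpness = sharpness, spike_count = spike_count),
            class = "papilla_spec")
}

# C1 radial bump: (1 - u^2)^q on u < 1, zero outside; q > 1 gives zero slope
# at the support edge so summed bumps keep their apices as strict maxima.
radial_bump <- function(u, q) {
  h <- pmax(0, 1 - u^2)
  h^q
}

#' Height function of a papilla over its base disk
#'
#' Fungiform: a smooth dome `height * (1 - (rho/R)^2)^p`, maximal at the
#' center, zero at the rim. Filiform: a central peak plus `spike_count`
#' radially arranged sub-peaks (the "crown"); sharpness scales the profile
#' exponents, hence peak curvature. Deterministic in the spec.
#'
#' @param spec a [papilla_spec()].
#' @return A vectorised `function(x, y)` returning heights in micrometres
#'   relative to the base surface (0 outside the base disk).
#' @export
papilla_heightfield <- function(spec) {
  cx <- spec$center[1]
  cy <- spec$center[2]
  R <- spec$base_radius
  h <- spec$height
  if (spec$type == "fungiform") {
    p <- max(0.6, spec$sharpness)
    function(x, y) {
      rho <- sqrt((x - cx)^2 + (y - cy)^2)
      h * radial_bump(rho / R, p)
    }
  } else {
    q <- max(1.1, 1.5 * spec$sharpness)
    k <- spec$spike_count
    r_central <- 0.38 * R
    ring <- 0.62 * R
    spike_r <- if (k > 0) min(0.22 * R, 0.9 * ring * sin(pi / k)) else 0
    ang <- if (k > 0) 2 * pi * (seq_len(k) - 1) / k else numeric(0)
    sx <- cx + ring * cos(ang)
    sy <- cy + ring * sin(ang)
    function(x, y) {
      z <- h * radial_bump(sqrt((x - cx)^2 + (y - cy)^2) / r_central, q)
      for (i in seq_len(k)) {
        z <- z + 0.85 * h *
          radial_bump(sqrt((x - sx[i])^2 + (y - sy[i])^2) / spike_r, q)
      }
      z
    }
  }
}

#' Participant profile with latent shape offsets
#'
#' @param participant_id identifier string.
#' @param gender `"F"` or `"M"`.
#' @param age age in years.
#' @param size_mult,sharpness_mult positive multipliers applied to papilla
#'   dimensions / sharpness for this participant.
#' @param spike_offset integer offset to the default crown spike count.
#' @return A list of class `participant_profile`.
#' @export
participant_profile <- function(participant_id, gender = c("F", "M"), age = 29,
                                size_mult = 1, sharpness_mult = 1,
                                spike_offset = 0L) {
  gender <- match.arg(gender)
  stopifnot(size_mult > 0, sharpness_mult > 0)
  structure(list(participant_id = as.character(participant_id),
                 gender = gender, age = as.numeric(age),
                 size_mult = size_mult, sharpness_mult = sharpness_mult,
                 spike_offset = as.integer(spike_offset)),
            class = "participant_profile")
}

#' Cohort-level effect sizes for synthetic participants
#'
#' Effects act multiplicatively on papilla sharpness/size through participant
#' profiles: female and younger profiles receive larger sharpness multipliers
#' (`exp(gender_sharpness)` for female, `exp(age_sharpness * (29.1 - age)/3.7)`
#' for age), on top of participant-specific lognormal offsets.
#'
#' @param gender_sharpness log-multiplier added for female participants.
#' @param age_sharpness log-multiplier per standard deviation of age below the
#'   cohort mean (29.1 y, sd 3.7 y).
#' @param participant_sharpness_sd,participant_size_sd lognormal sd of
#'   participant-specific sharpness/size offsets.
#' @param spike_count_jitter max absolute participant offset of the crown
#'   spike count.
#' @return A list of class `cohort_effects`.
#' @export
cohort_effects <- function(gender_sharpness = 0.30, age_sharpness = 0.20,
                           participant_sharpness_sd = 0.25,
                           participant_size_sd = 0.10,
                           spike_count_jitter = 1L) {
  stopifnot(participant_sharpness_sd >= 0, participant_size_sd >= 0,
            spike_count_jitter >= 0)
  structure(list(gender_sharpness = gender_sharpness,
                 age_sharpness = age_sharpness,
                 participant_sharpness_sd = participant_sharpness_sd,
                 participant_size_sd = participant_size_sd,
                 spike_count_jitter = as.integer(spike_count_jitter)),
            class = "cohort_effects")
}

#' @rdname cohort_effects
#' @export
cohort_effects_null <- function() {
  cohort_effects(gender_sharpness = 0, age_sharpness = 0,
                 participant_sharpness_sd = 0, participant_size_sd = 0,
                 spike_count_jitter = 0L)
}

# per-papilla biological variability (lognormal sd), fixed package-wide
papilla_jitter <- list(radius_sd = 0.15, height_sd = 0.25, sharpness_sd = 0.15)

# dart-throwing placement: uniform centers, base disks pairwise disjoint
# (plus min_separation gap); bounded retries
place_papillae <- function(width, depth, radii, min_separation, max_tries) {
  n <- length(radii)
  centers <- matrix(NA_real_, n, 2L)
  tries <- 0L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("placement error: could not place ", n,
             " papillae without overlap; reduce density or enlarge surface")
      }
      cx <- runif(1, radii[i], width - radii[i])
      cy <- runif(1, radii[i], depth - radii[i])
      if (i == 1L) { centers[i, ] <- c(cx, cy); break }
      prev <- seq_len(i - 1L)
      gap <- sqrt((centers[prev, 1] - cx)^2 + (centers[prev, 2] - cy)^2) -
        (radii[prev] + radii[i] + min_separation)
      if (all(gap > 0)) { centers[i, ] <- c(cx, cy); break }
    }
  }
  centers
}

#' Generate an annotated synthetic tongue surface
#'
#' Builds a regular-grid triangulated sheet with low-frequency undulation,
#' plants papillae by dart throwing (base disks pairwise disjoint), and applies
#' Gaussian displacement noise along vertex normals. The returned annotation
#' list exactly matches the planted papillae. Deterministic given `seed`.
#'
#' @param width,depth surface extent in micrometres.
#' @param counts named vector/list of planted papilla counts
#'   (`fungiform`, `filiform`); if `NULL`, derived from the densities.
#' @param fungiform_density,filiform_density papillae per cm^2 used when
#'   `counts` is `NULL` (a human tongue carries roughly 100-200 filiform per
#'   cm^2).
#' @param participant optional [participant_profile()] whose latent offsets
#'   scale papilla size/sharpness.
#' @param noise_sd Gaussian displacement noise sd (um) along vertex normals,
#'   mimicking residual reconstruction roughness.
#' @param mesh_pitch grid spacing (um).
#' @param undulation_amplitude,undulation_wavelength base-sheet undulation
#'   (um).
#' @param min_separation extra gap (um) required between papilla base disks.
#' @param jitter_scale multiplier on the per-papilla biological size/sharpness
#'   variability (lognormal sd); `0` plants every papilla exactly at its type
#'   specification.
#' @param seed integer seed.
#' @return An `annotated_surface`: list with `mesh` ([tri_mesh()]),
#'   `papillae` (tibble of planted specs incl. apex coordinates),
#'   `participant`, and generation parameters.
#' @export
generate_surface <- function(width = 5000, depth = 5000, counts = NULL,
                             fungiform_density = 15, filiform_density = 150,
                             participant = NULL, noise_sd = 2,
                             mesh_pitch = 25, undulation_amplitude = 30,
                             undulation_wavelength = 3500,
                             min_separation = 0, jitter_scale = 1, seed = 1) {
  stopifnot(width > 0, depth > 0, mesh_pitch > 0, noise_sd >= 0,
            jitter_scale >= 0)
  if (is.null(counts)) {
    area_cm2 <- width * depth / 1e8
    counts <- c(fungiform = round(fungiform_density * area_cm2),
                filiform = round(filiform_density * area_cm2))
  }
  n_fungi <- as.integer(counts[["fungiform"]] %||% 0L)
  n_fili <- as.integer(counts[["filiform"]] %||% 0L)
  stopifnot(n_fungi >= 0, n_fili >= 0)

  size_mult <- participant$size_mult %||% 1
  sharp_mult <- participant$sharpness_mult %||% 1
  spike_off <- participant$spike_offset %||% 0L

  with_seed(seed, {
    # draw per-papilla specs (type defaults x participant x biological jitter)
    types <- c(rep("fungiform", n_fungi), rep("filiform", n_fili))
    np <- length(types)
    specs <- vector("list", np)
    radii <- numeric(np)
    for (i in seq_len(np)) {
      def <- papilla_defaults[[types[i]]]
      br <- def$base_radius * size_mult *
        exp(rnorm(1, 0, jitter_scale * papilla_jitter$radius_sd))
      ht <- def$height * size_mult *
        exp(rnorm(1, 0, jitter_scale * papilla_jitter$height_sd))
      sh <- sharp_mult * exp(rnorm(1, 0, jitter_scale * papilla_jitter$sharpness_sd))
      sc <- if (types[i] == "filiform") {
        jit <- if (jitter_scale > 0) sample(-1:1, 1L) else 0L
        max(3L, def$spike_count + spike_off + jit)
      } else 0L
      specs[[i]] <- list(type = types[i], base_radius = br, height = ht,
                         sharpness = sh, spike_count = sc)
      radii[i] <- br
    }
    centers <- if (np > 0) {
      place_papillae(width, depth, radii, min_separation,
                     max_tries = max(2000L, 200L * np))
    } else matrix(numeric(0), 0L, 2L)

    # base grid + undulation
    xs <- seq(0, width, by = mesh_pitch)
    ys <- seq(0, depth, by = mesh_pitch)
    nx <- length(xs)
    ny <- length(ys)
    g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
    ph <- runif(3, 0, 2 * pi)
    lam <- undulation_wavelength
    z <- undulation_amplitude * (
      0.7 * sin(2 * pi * g$x / lam + ph[1]) * sin(2 * pi * g$y / (0.83 * lam) + ph[2]) +
      0.3 * sin(2 * pi * (g$x + g$y) / (0.57 * lam) + ph[3]))
    undulation_at <- function(px, py) {
      undulation_amplitude * (
        0.7 * sin(2 * pi * px / lam + ph[1]) * sin(2 * pi * py / (0.83 * lam) + ph[2]) +
        0.3 * sin(2 * pi * (px + py) / (0.57 * lam) + ph[3]))
    }

    # add papilla heightfields (only over each base disk's bounding box)
    ann <- vector("list", np)
    for (i in seq_len(np)) {
      sp <- papilla_spec(specs[[i]]$type, centers[i, ],
                         base_radius = specs[[i]]$base_radius,
                         height = specs[[i]]$height,
                         sharpness = specs[[i]]$sharpness,
                         spike_count = specs[[i]]$spike_count)
      hf <- papilla_heightfield(sp)
      ix <- which(xs >= centers[i, 1] - radii[i] & xs <= centers[i, 1] + radii[i])
      iy <- which(ys >= centers[i, 2] - radii[i] & ys <= centers[i, 2] + radii[i])
      rows <- as.vector(outer(ix, (iy - 1L) * nx, `+`))
      z[rows] <- z[rows] + hf(g$x[rows], g$y[rows])
      ann[[i]] <- tibble::tibble(
        type = sp$type, x = sp$center[1], y = sp$center[2],
        base_radius = sp$base_radius, height = sp$height,
        sharpness = sp$sharpness, spike_count = sp$spike_count,
        apex_x = sp$center[1], apex_y = sp$center[2],
        apex_z = undulation_at(sp$center[1], sp$center[2]) + sp$height)
    }
    papillae <- if (np > 0) dplyr::bind_rows(ann) else tibble::tibble(
      type = character(), x = numeric(), y = numeric(),
      base_radius = numeric(), height = numeric(), sharpness = numeric(),
      spike_count = integer(), apex_x = numeric(), apex_y = numeric(),
      apex_z = numeric())

    # grid triangulation, CCW seen from +z
    i0 <- rep(seq_len(nx - 1L), ny - 1L) + rep((seq_len(ny - 1L) - 1L) * nx, each = nx - 1L)
    tri <- rbind(cbind(i0, i0 + 1L, i0 + nx),
                 cbind(i0 + 1L, i0 + nx + 1L, i0 + nx))
    mesh <- tri_mesh(cbind(g$x, g$y, z), tri, validate = FALSE)

    if (noise_sd > 0) {
      nrm <- vertex_normals(mesh)
      disp <- rnorm(nrow(mesh$vertices), 0, noise_sd)
      mesh$vertices <- mesh$vertices + nrm * disp
    }

    structure(list(mesh = mesh, papillae = papillae,
                   participant = participant, noise_sd = noise_sd,
                   width = width, depth = depth, mesh_pitch = mesh_pitch,
                   seed = seed),
              class = "annotated_surface")
  })
}

#' @export
print.annotated_surface <- function(x, ...) {
  cat(sprintf("<annotated_surface> %.1f x %.1f mm, pitch %g um, noise sd %g um\n",
              x$width / 1000, x$depth / 1000, x$mesh_pitch, x$noise_sd))
  cat(sprintf("  %d planted papillae (%d fungiform, %d filiform)\n",
              nrow(x$papillae), sum(x$papillae$type == "fungiform"),
              sum(x$papillae$type == "filiform")))
  print(x$mesh)
  invisible(x)
}

#' Generate a synthetic participant cohort
#'
#' Draws participant profiles (gender, age, latent shape offsets) and one
#' annotated surface per participant, sized to host the requested number of
#' segments at the study's class proportions. Female and younger profiles
#' receive larger sharpness multipliers. Ages straddle the cut-off of 29 years
#' (young <= 28, old >= 29) so both age groups are populated.
#'
#' @param n_participants number of participants (>= 2); the study template is
#'   a cohort of 15 (9 female, mean age 29.1 y, sd 3.7 y).
#' @param segments_per_participant target labelled segments per participant.
#' @param class_ratio unnormalised class proportions used to split the target
#'   counts; default mirrors the 414:1489:190
#'   fungiform:filiform:none composition of the study dataset.
#' @param effects a [cohort_effects()]; use [cohort_effects_null()] for a
#'   cohort with no injected participant/gender/age structure.
#' @param female_fraction fraction of female participants (9/15 by default).
#' @param noise_sd,mesh_pitch passed to [generate_surface()].
#' @param seed integer seed; the cohort is a pure function of (config, seed).
#' @return A `papilla_cohort`: list with `surfaces` (list of
#'   `annotated_surface`) and `metadata` (tibble: participant, gender, age,
#'   age_group, latent multipliers).
#' @export
generate_cohort <- function(n_participants = 15,
                            segments_per_participant = 60,
                            class_ratio = c(fungiform = 414, filiform = 1489,
                                            none = 190),
                            effects = cohort_effects(),
                            female_fraction = 9 / 15,
                            noise_sd = 2, mesh_pitch = 25, seed = 1) {
  if (n_participants < 2) stop("argument error: need at least 2 participants")
  if (!inherits(effects, "cohort_effects")) stop("argument error: effects")
  frac <- class_ratio / sum(class_ratio)
  n_fungi <- max(2L, round(segments_per_participant * frac[["fungiform"]]))
  n_fili <- max(2L, round(segments_per_participant * frac[["filiform"]]))

  with_seed(seed, {
    n_f <- round(female_fraction * n_participants)
    genders <- sample(c(rep("F", n_f), rep("M", n_participants - n_f)))
    # alternate young/old draws around the cut-off for a near-equal split
    ages <- numeric(n_participants)
    for (i in seq_len(n_participants)) {
      if (i %% 2 == 1) {
        ages[i] <- round(min(28, 28 - abs(rnorm(1, 0, 3.0))))
      } else {
        ages[i] <- round(max(29, 29 + abs(rnorm(1, 0, 3.2))))
      }
    }
    ages <- pmin(pmax(ages, 22), 37)

    profiles <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      sharp <- exp(effects$gender_sharpness * (genders[i] == "F") +
                   effects$age_sharpness * (29.1 - ages[i]) / 3.7 +
                   rnorm(1, 0, effects$participant_sharpness_sd))
      size <- exp(rnorm(1, 0, effects$participant_size_sd))
      spike <- if (effects$spike_count_jitter > 0) {
        sample(seq(-effects$spike_count_jitter, effects$spike_count_jitter), 1L)
      } else 0L
      profiles[[i]] <- participant_profile(
        participant_id = sprintf("P%02d", i), gender = genders[i],
        age = ages[i], size_mult = size, sharpness_mult = sharp,
        spike_offset = spike)
    }

    # size each surface so the requested papillae fit at ~22% disk packing
    disk_area <- n_fungi * pi * papilla_defaults$fungiform$base_radius^2 +
      n_fili * pi * papilla_defaults$filiform$base_radius^2
    side <- max(2500, ceiling(sqrt(disk_area / 0.22)))

    surfaces <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      surfaces[[i]] <- generate_surface(
        width = side, depth = side,
        counts = c(fungiform = n_fungi, filiform = n_fili),
        participant = profiles[[i]], noise_sd = noise_sd,
        mesh_pitch = mesh_pitch, seed = derive_seed(seed, i))
    }

    metadata <- tibble::tibble(
      participant = vapply(profiles, `[[`, "", "participant_id"),
      gender = genders,
      age = ages,
      age_group = ifelse(ages <= 28, "young", "old"),
      size_mult = vapply(profiles, `[[`, 0, "size_mult"),
      sharpness_mult = vapply(profiles, `[[`, 0, "sharpness_mult"),
      spike_offset = vapply(profiles, `[[`, 0L, "spike_offset"))

    structure(list(surfaces = surfaces, metadata = metadata, seed = seed,
                   segments_per_participant = segments_per_participant,
                   class_ratio = class_ratio, effects = effects),
              class = "papilla_cohort")
  })
}

#' @export
print.papilla_cohort <- function(x, ...) {
  cat(sprintf("<papilla_cohort> %d participants (%d F / %d M), ages %d-%d\n",
              nrow(x$metadata), sum(x$metadata$gender == "F"),
              sum(x$metadata$gender == "M"), min(x$metadata$age),
              max(x$metadata$age)))
  invisible(x)
}
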