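#' Configuration for the synthetic landmark-cohort generator
#'
#' Defaults emulate a desk-scale version of a multi-syndrome 3D facial
#' landmark study: bilaterally structured 65-landmark faces, Gaussian
#' within-class variation in the symmetric shape subspace, class mean offsets
#' of controllable severity and geometry, cubic growth and additive sex
#' effects, small bilateral asymmetry, family structure, and "unaffected"
#' relatives carrying an attenuated fraction of their affected family member's
#' syndromic offset.
#'
#' @param n_landmarks total landmarks; `n_midline` of them lie on the
#'   mid-sagittal plane and the rest form bilateral pairs.
#' @param n_midline number of midline landmarks.
#' @param n_syndromes number of syndromic classes.
#' @param n_per_syndrome subjects per syndrome (scalar or per-class vector).
#' @param n_unaffected number of unrelated, unaffected subjects.
#' @param severity_scale mean-offset magnitude in Procrustes units; per-class
#'   severities are `severity_scale` times multipliers evenly spaced in
#'   `[0.5, 1.5]`.
#' @param distinctiveness_mode `"orthogonal"` (mutually orthogonal class mean
#'   directions) or `"clustered"` (directions at `cluster_angle` radians from
#'   a common axis).
#' @param cluster_angle angle (radians) for `"clustered"` mode.
#' @param within_sigma RMS within-class shape deviation (Procrustes units).
#' @param within_mode `"spherical"` or `"integrated"` within-class covariance.
#' @param within_decay eigenvalue decay rate `rho` in `(0, 1]` for
#'   `"integrated"` covariance; smaller values concentrate variance on fewer
#'   axes (higher integratedness).
#' @param age_range age range in years (uniform sampling).
#' @param growth_effect magnitude of the cubic growth trajectory.
#' @param sex_effect magnitude of the additive sex contrast.
#' @param asymmetry_noise RMS deviation in the antisymmetric subspace.
#' @param n_families number of families contributing one unaffected relative
#'   each (each family also contains one syndromic member).
#' @param relative_attenuation fraction `a` in `[0, 1]` of the family
#'   syndrome's mean offset carried by relatives.
#' @param family_shared_effect RMS magnitude of the shape effect shared by
#'   members of the same family.
#' @param severity_variance_coupling if `TRUE`, within-class deviations are
#'   scaled by `1 + coupling * s_k`, making severe syndromes more variable.
#' @param coupling coupling constant `c` (default 10).
#' @param seed integer seed; all randomness derives from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_landmarks = 65, n_midline = 5,
                             n_syndromes = 10, n_per_syndrome = 20,
                             n_unaffected = 200,
                             severity_scale = 0.02,
                             distinctiveness_mode = c("orthogonal", "clustered"),
                             cluster_angle = pi / 6,
                             within_sigma = 0.05,
                             within_mode = c("spherical", "integrated"),
                             within_decay = 0.7,
                             age_range = c(1, 70),
                             growth_effect = 0.05,
                             sex_effect = 0.015,
                             asymmetry_noise = 0.01,
                             n_families = 20,
                             relative_attenuation = 0.5,
                             family_shared_effect = 0.01,
                             severity_variance_coupling = FALSE,
                             coupling = 10,
                             seed = 20200601) {
  distinctiveness_mode <- match.arg(distinctiveness_mode)
  within_mode <- match.arg(within_mode)
  stopifnot((n_landmarks - n_midline) %% 2 == 0,
            severity_scale >= 0, within_sigma >= 0, asymmetry_noise >= 0,
            growth_effect >= 0, sex_effect >= 0, family_shared_effect >= 0,
            relative_attenuation >= 0, relative_attenuation <= 1,
            within_decay > 0, within_decay <= 1)
  cfg <- list(n_landmarks = n_landmarks, n_midline = n_midline,
              n_syndromes = n_syndromes, n_per_syndrome = n_per_syndrome,
              n_unaffected = n_unaffected, severity_scale = severity_scale,
              distinctiveness_mode = distinctiveness_mode,
              cluster_angle = cluster_angle,
              within_sigma = within_sigma, within_mode = within_mode,
              within_decay = within_decay, age_range = age_range,
              growth_effect = growth_effect, sex_effect = sex_effect,
              asymmetry_noise = asymmetry_noise, n_families = n_families,
              relative_attenuation = relative_attenuation,
              family_shared_effect = family_shared_effect,
              severity_variance_coupling = severity_variance_coupling,
              coupling = coupling, seed = seed)
  structure(cfg, class = "generator_config")
}

#' Build a bilaterally symmetric face-like landmark template
#'
#' Paired landmarks are mirrored across the `x = 0` plane; midline landmarks
#' lie exactly on it. Points sit on the front half of an ellipsoid with
#' deterministic seeded jitter, centred and scaled to unit centroid size.
#'
#' @param n_landmarks total landmarks.
#' @param n_midline number of midline landmarks.
#' @param seed integer seed.
#' @return A list with `template` (`k x 3` matrix) and `pairing`
#'   ([symmetry_pairing()]).
#' @export
make_template <- function(n_landmarks = 65, n_midline = 5, seed = 1) {
  if ((n_landmarks - n_midline) %% 2 != 0) {
    stop("n_landmarks - n_midline must be even (bilateral pairs)",
         call. = FALSE)
  }
  n_pairs <- (n_landmarks - n_midline) / 2
  set.seed(seed)
  # right-side points on the front of an ellipsoid (x lateral, y vertical,
  # z depth)
  y <- runif(n_pairs, -0.9, 0.9)
  z <- runif(n_pairs, -0.6, 0.6)
  x <- 0.9 * sqrt(pmax(0.05, 1 - (y / 1.1)^2 - (z / 0.8)^2)) +
    runif(n_pairs, 0.02, 0.1)
  right <- cbind(x, y, z)
  left <- cbind(-x, y, z)
  ym <- seq(-1, 1, length.out = max(n_midline, 2))[seq_len(n_midline)]
  mid <- cbind(0, ym, 0.8 * (1 - ym^2) + runif(n_midline, -0.05, 0.05))
  template <- rbind(right, left, mid)
  template <- sweep(template, 2, colMeans(template))
  template <- template / sqrt(sum(template^2))
  pairing <- symmetry_pairing(
    cbind(n_pairs + seq_len(n_pairs), seq_len(n_pairs)),  # (left, right)
    midline = 2 * n_pairs + seq_len(n_midline),
    k = n_landmarks
  )
  list(template = template, pairing = pairing)
}

# orthonormal basis (3k x m) of the reflect-relabel symmetric (or
# antisymmetric) subspace, seeded by the caller
symmetry_basis <- function(pairing, k, antisymmetric = FALSE) {
  n_pairs <- nrow(pairing$pairs)
  m <- if (antisymmetric) 3 * n_pairs + length(pairing$midline)
       else 3 * n_pairs + 2 * length(pairing$midline)
  raw <- matrix(rnorm(3 * k * m), 3 * k, m)
  proj <- apply(raw, 2, function(v) {
    w <- reflect_relabel(v, pairing)
    if (antisymmetric) (v - w) / 2 else (v + w) / 2
  })
  qr_out <- qr(proj)
  qr.Q(qr_out)[, seq_len(qr_out$rank), drop = FALSE]
}

#' Generate a synthetic landmark cohort
#'
#' Draws a cohort according to a [generator_config()]: per-syndrome mean
#' offsets `s_k u_k` in the symmetric shape subspace, Gaussian within-class
#' deviations, a fixed cubic growth trajectory, an additive sex contrast,
#' antisymmetric noise, family-shared effects, relatives carrying `a * delta`
#' of their family syndrome, and a random rigid motion plus scale per subject
#' so superimposition is genuinely exercised. All latent quantities are
#' recorded in the ground truth.
#'
#' @param config a [generator_config()].
#' @return A list of class `synthetic_cohort`: `$cohort` (a `cohort`) and
#'   `$truth` (per-subject and per-syndrome tibbles plus latent directions).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  tpl <- make_template(cfg$n_landmarks, cfg$n_midline, seed = cfg$seed)
  template <- tpl$template
  pairing <- tpl$pairing
  k <- cfg$n_landmarks
  t_vec <- config_to_vector(template)

  # latent structure stream
  set.seed(cfg$seed + 1L)
  V_sym <- symmetry_basis(pairing, k)
  V_asym <- symmetry_basis(pairing, k, antisymmetric = TRUE)
  m <- ncol(V_sym)
  g <- cfg$n_syndromes
  if (cfg$distinctiveness_mode == "orthogonal" && g > m) {
    stop("orthogonal mode supports at most ", m, " syndromes (symmetric ",
         "subspace dimension)", call. = FALSE)
  }
  dirs <- if (cfg$distinctiveness_mode == "orthogonal") {
    V_sym[, seq_len(g), drop = FALSE]
  } else {
    b <- V_sym[, 1]
    w <- V_sym[, 1 + seq_len(g), drop = FALSE]
    u <- cos(cfg$cluster_angle) * matrix(b, 3 * k, g) +
      sin(cfg$cluster_angle) * w
    u
  }
  mult <- if (g > 1) seq(0.5, 1.5, length.out = g) else 1
  s_k <- cfg$severity_scale * mult
  u_age <- V_sym %*% rnorm(m); u_age <- u_age / sqrt(sum(u_age^2))
  u_sex <- V_sym %*% rnorm(m); u_sex <- u_sex / sqrt(sum(u_sex^2))
  eigvals <- if (cfg$within_mode == "spherical") rep(1 / m, m) else {
    e <- cfg$within_decay^(seq_len(m) - 1); e / sum(e)
  }
  W <- V_sym %*% (t(matrix(rnorm(m * m), m, m)) |> qr() |> qr.Q())
  # columns of W: random orthonormal directions inside the symmetric subspace

  n_per <- rep_len(cfg$n_per_syndrome, g)
  syndromes <- sprintf("syndrome_%02d", seq_len(g))

  # subject composition
  groups <- c(rep(syndromes, n_per), rep("unaffected", cfg$n_unaffected))
  n_core <- length(groups)
  n_fam <- cfg$n_families
  if (n_fam > sum(n_per)) {
    stop("n_families exceeds the number of syndromic subjects", call. = FALSE)
  }

  set.seed(cfg$seed + 2L)
  syn_idx <- which(groups != "unaffected")
  fam_members <- if (n_fam > 0) syn_idx[round(seq(1, length(syn_idx),
                                                  length.out = n_fam))]
                 else integer()
  n_total <- n_core + n_fam
  ids <- sprintf("S%04d", seq_len(n_total))
  family_id <- rep(NA_character_, n_total)
  family_id[fam_members] <- sprintf("F%03d", seq_len(n_fam))
  status <- ifelse(groups == "unaffected", "unaffected", "molecular")
  group_all <- c(groups, groups[fam_members])
  status_all <- c(status, rep("relative", n_fam))
  family_all <- c(family_id[seq_len(n_core)],
                  sprintf("F%03d", seq_len(n_fam)))
  atten <- c(rep(NA_real_, n_core), rep(cfg$relative_attenuation, n_fam))

  age <- runif(n_total, cfg$age_range[1], cfg$age_range[2])
  sex <- sample(c("female", "male"), n_total, replace = TRUE)
  fam_effects <- matrix(0, 3 * k, n_fam)
  if (n_fam > 0) {
    fam_effects <- V_sym %*% matrix(rnorm(m * n_fam,
                                          sd = cfg$family_shared_effect /
                                            sqrt(m)), m, n_fam)
  }

  t_age <- function(a) {
    t <- 2 * (a - cfg$age_range[1]) / diff(cfg$age_range) - 1
    0.6 * t + 0.3 * t^2 + 0.1 * t^3
  }

  draw_within <- function(scale) {
    W %*% (rnorm(m) * sqrt(eigvals) * scale)
  }

  shapes_true <- matrix(NA_real_, n_total, 3 * k)
  s_of <- function(grp) if (grp == "unaffected") 0 else
    s_k[match(grp, syndromes)]
  for (i in seq_len(n_total)) {
    grp <- group_all[i]
    s <- s_of(grp)
    a_i <- if (status_all[i] == "relative") cfg$relative_attenuation else
      if (grp == "unaffected") 0 else 1
    delta <- if (grp == "unaffected") 0 else
      a_i * s * dirs[, match(grp, syndromes)]
    vscale <- cfg$within_sigma *
      (if (cfg$severity_variance_coupling) 1 + cfg$coupling * a_i * s else 1)
    fam_eff <- 0
    if (!is.na(family_all[i])) {
      fam_eff <- fam_effects[, match(family_all[i],
                                     sprintf("F%03d", seq_len(n_fam)))]
    }
    asym <- V_asym %*% rnorm(ncol(V_asym),
                             sd = cfg$asymmetry_noise / sqrt(ncol(V_asym)))
    shapes_true[i, ] <- t_vec + delta + draw_within(vscale) + fam_eff +
      cfg$growth_effect * t_age(age[i]) * u_age +
      cfg$sex_effect * (if (sex[i] == "male") 0.5 else -0.5) * u_sex +
      asym
  }

  # per-subject similarity transform so GPA has real work to do
  set.seed(cfg$seed + 3L)
  configs <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    mcoords <- vector_to_config(shapes_true[i, ])
    R <- random_rotation()
    sc <- exp(runif(1, log(0.8), log(1.25)))
    tr <- rnorm(3, sd = 0.5)
    configs[[i]] <- sweep(sc * mcoords %*% R, 2, tr, "+")
  }

  meta <- tibble::tibble(
    subject_id = ids,
    age = age,
    sex = sex,
    syndrome = group_all,
    diagnosis_status = status_all,
    family_id = family_all,
    camera = "cam1",
    race = NA_character_,
    ethnicity = NA_character_
  )
  cohort <- assemble_cohort(landmark_set(configs, ids), meta,
                            pairing = pairing)

  truth <- list(
    per_subject = tibble::tibble(
      subject_id = ids, group = group_all, status = status_all,
      family_id = family_all,
      s = vapply(group_all, s_of, numeric(1)) *
        ifelse(status_all == "relative", cfg$relative_attenuation,
               ifelse(group_all == "unaffected", 0, 1)),
      attenuation = atten, age = age, sex = sex
    ),
    per_syndrome = tibble::tibble(syndrome = syndromes, s = s_k,
                                  multiplier = mult),
    directions = dirs, template = template, pairing = pairing,
    config = cfg
  )
  structure(list(cohort = cohort, truth = truth), class = "synthetic_cohort")
}

random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_out)
  Q <- Q %*% diag(sign(diag(qr.R(qr_out))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> seed ", x$truth$config$seed, "\n", sep = "")
  print(x$cohort)
  invisible(x)
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Emits `landmarks.tps`, `metadata.csv`, `pairing.csv` and
#' `ground_truth.csv` into `dir`, loadable with the package readers.
#'
#' @param synth a [generate_cohort()] result (or a plain `cohort`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(synth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- if (inherits(synth, "synthetic_cohort")) synth$cohort else synth
  write_tps(cohort$landmarks, file.path(dir, "landmarks.tps"))
  readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"))
  if (!is.null(cohort$pairing)) {
    write_pairing_csv(cohort$pairing, file.path(dir, "pairing.csv"))
  }
  if (inherits(synth, "synthetic_cohort")) {
    readr::write_csv(synth$truth$per_subject,
                     file.path(dir, "ground_truth.csv"))
  }
  invisible(dir)
}
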