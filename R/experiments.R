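#' Prepare standardized shape data from a cohort
#'
#' Runs the preprocessing chain: GPA superimposition, optional outlier
#' removal, object-symmetry decomposition, and age/sex standardization.
#' Subjects with missing age or sex are excluded with a warning. The
#' classification input can be the symmetric component (default, which
#' performed best in practice), the unsymmetrized aligned shapes, or both
#' components combined.
#'
#' @param cohort a `cohort` with a symmetry pairing (unless
#'   `use = "unsymmetrized"`).
#' @param use `"symmetric"`, `"unsymmetrized"` or `"combined"`.
#' @param outlier_z robust z-score cut for outlier removal (`Inf` keeps all).
#' @param standardize_pooled fit one pooled age/sex model on all subjects
#'   (default) rather than on unaffected subjects only.
#' @return A list with `shapes` (standardized matrix), `meta` (possibly
#'   subset), `aligned` (the `aligned_shapes`), `model` (the age/sex fit),
#'   and `outliers` (the outlier report).
#' @export
prepare_shapes <- function(cohort, use = c("symmetric", "unsymmetrized",
                                           "combined"),
                           outlier_z = Inf, standardize_pooled = TRUE) {
  use <- match.arg(use)
  aligned <- gpa(cohort$landmarks)
  outliers <- detect_outliers(aligned, z_cut = outlier_z)
  keep_ids <- outliers$subject_id[!outliers$flag]
  meta <- cohort$metadata
  ok_cov <- !is.na(meta$age) & !is.na(meta$sex)
  if (any(!ok_cov)) {
    warning(sum(!ok_cov), " subject(s) with missing age or sex excluded ",
            "from standardization and classification", call. = FALSE)
  }
  keep <- meta$subject_id %in% keep_ids & ok_cov
  meta <- meta[keep, ]

  raw <- if (use == "unsymmetrized") {
    aligned$shapes
  } else {
    if (is.null(cohort$pairing)) {
      stop("cohort has no symmetry pairing; use = 'unsymmetrized' only",
           call. = FALSE)
    }
    dec <- symmetrize(aligned, cohort$pairing)
    if (use == "symmetric") dec$symmetric else
      cbind(dec$symmetric, dec$asymmetric)
  }
  raw <- raw[match(meta$subject_id, rownames(raw)), , drop = FALSE]

  fit_on <- if (standardize_pooled) seq_len(nrow(meta)) else
    which(meta$syndrome == "unaffected")
  model <- fit_age_sex_model(raw[fit_on, , drop = FALSE],
                             meta$age[fit_on], meta$sex[fit_on])
  shapes <- standardize(model, raw, meta$age, meta$sex)
  rownames(shapes) <- meta$subject_id
  list(shapes = shapes, meta = meta, aligned = aligned, model = model,
       outliers = outliers)
}

#' Classification accuracy versus number of syndromes
#'
#' Repeatedly draws random subsets of syndromes of each requested size, runs
#' cross-validated classification on the subset (plus the unaffected class if
#' requested), and records the mean top-1 sensitivity, emulating
#' classification-permutation experiments over 2 to 50 syndromes.
#'
#' @param shapes standardized shape matrix, rows named by subject.
#' @param meta metadata tibble aligned with `shapes`.
#' @param sizes integer vector of syndrome-subset sizes.
#' @param reps random subsets per size (default 250).
#' @param method `"cva"` (default, the parametric classifier) or `"hdrda"`.
#' @param include_unaffected include the unaffected class in each task.
#' @param scheme,k,seed cross-validation controls.
#' @param params [hdrda_params()] when `method = "hdrda"`.
#' @return A tibble with columns `size`, `rep`, `mean_sensitivity`.
#' @export
syndrome_count_simulation <- function(shapes, meta, sizes, reps = 250,
                                      method = c("cva", "hdrda"),
                                      include_unaffected = FALSE,
                                      scheme = "kfold", k = 5, seed = 1,
                                      params = hdrda_params()) {
  method <- match.arg(method)
  core <- meta$diagnosis_status != "relative"
  syn <- sort(setdiff(unique(meta$syndrome[core]), "unaffected"))
  set.seed(seed)
  out <- list()
  for (size in sizes) {
    if (size > length(syn)) {
      warning("size ", size, " exceeds the ", length(syn),
              " available syndromes; skipped", call. = FALSE)
      next
    }
    for (r in seq_len(reps)) {
      chosen <- if (size == length(syn)) syn else sample(syn, size)
      keep <- core & (meta$syndrome %in% chosen |
                        (include_unaffected & meta$syndrome == "unaffected"))
      # fold assignment is fixed per size so the replicate-to-replicate
      # variation is the random syndrome subset alone
      rep_out <- crossvalidate(shapes[keep, , drop = FALSE], meta[keep, ],
                               method = method, params = params,
                               scheme = scheme, k = k, seed = seed + size)
      cls <- tidy(rep_out)
      sens <- mean(cls$sensitivity[cls$class != "unaffected"])
      out[[length(out) + 1L]] <- tibble::tibble(
        size = size, rep = r, mean_sensitivity = sens)
    }
  }
  dplyr::bind_rows(out)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load (or accept) a cohort, GPA, outlier screening,
#' symmetrization, age/sex standardization, Procrustes MANOVA, minimum-n
#' filtering, two-group CVA, multi-class HDRDA and CVA classification with and
#' without the unaffected class, per-syndrome shape statistics, determinants
#' analysis, and the unaffected-relatives analysis. All tables are written as
#' CSV to `out_dir` together with the resolved configuration.
#'
#' @param config a named list (or path to a YAML file) with any of:
#'   `landmarks`, `metadata`, `pairing` (file paths) or `cohort` (a `cohort`
#'   object); `out_dir`; `use` (shape component); `min_n`; `lambda`, `gamma`;
#'   `cv` (`"family"` or `"kfold"`), `k`; `n_perm`; `outlier_z`; `seed`.
#' @return A list of class `pipeline_result` with all stage outputs
#'   (invisibly writes CSVs when `out_dir` is given).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(use = "symmetric", min_n = 10, lambda = 0.5, gamma = 1e-3,
                   cv = "family", k = 20, n_perm = 199, outlier_z = Inf,
                   seed = 1, out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("load", {
    if (!is.null(cfg$cohort)) cfg$cohort else {
      lms <- if (grepl("\\.tps$", cfg$landmarks)) read_tps(cfg$landmarks)
             else read_landmarks_csv(cfg$landmarks)
      md <- read_metadata_csv(cfg$metadata)
      pr <- if (!is.null(cfg$pairing)) read_pairing_csv(cfg$pairing) else NULL
      assemble_cohort(lms, md, pr)
    }
  })

  prep <- stage("preprocess", {
    prepare_shapes(cohort, use = cfg$use, outlier_z = cfg$outlier_z)
  })
  shapes <- prep$shapes
  meta <- prep$meta

  manova_tab <- stage("manova", {
    core <- meta$diagnosis_status != "relative"
    procrustes_manova(shapes_for_manova(prep), meta[core, ],
                      terms = c("poly(age, 3)", "sex", "syndrome"),
                      n_perm = cfg$n_perm, seed = cfg$seed)
  })

  filt <- stage("min_n_filter", {
    counts <- table(meta$syndrome[meta$diagnosis_status != "relative" &
                                    meta$syndrome != "unaffected"])
    dropped <- names(counts)[counts < cfg$min_n]
    keep <- meta$syndrome == "unaffected" | !(meta$syndrome %in% dropped)
    list(shapes = shapes[keep, , drop = FALSE], meta = meta[keep, ],
         dropped = dropped)
  })
  shapes <- filt$shapes
  meta <- filt$meta
  params <- hdrda_params(cfg$lambda, cfg$gamma)

  two_group <- stage("two_group_cva", {
    two_group_cva(shapes, meta, scheme = "kfold", k = cfg$k, seed = cfg$seed)
  })

  cv_args <- list(scheme = if (cfg$cv == "family") "family" else "kfold",
                  k = cfg$k, seed = cfg$seed)
  core <- meta$diagnosis_status != "relative"
  syn_only <- core & meta$syndrome != "unaffected"

  full_hdrda <- stage("hdrda_full", {
    do.call(crossvalidate, c(list(shapes[core, , drop = FALSE], meta[core, ],
                                  method = "hdrda", params = params), cv_args))
  })
  syn_hdrda <- stage("hdrda_syndrome_only", {
    do.call(crossvalidate, c(list(shapes[syn_only, , drop = FALSE],
                                  meta[syn_only, ],
                                  method = "hdrda", params = params), cv_args))
  })
  full_cva <- stage("cva_full", {
    do.call(crossvalidate, c(list(shapes[core, , drop = FALSE], meta[core, ],
                                  method = "cva"), cv_args))
  })
  syn_cva <- stage("cva_syndrome_only", {
    do.call(crossvalidate, c(list(shapes[syn_only, , drop = FALSE],
                                  meta[syn_only, ],
                                  method = "cva"), cv_args))
  })

  stats_tab <- stage("syndrome_stats", {
    syndrome_stats(shapes, meta, min_n = cfg$min_n)
  })

  dets <- stage("determinants", {
    sens <- dplyr::inner_join(
      dplyr::select(tidy(full_hdrda), "class", hdrda = "sensitivity"),
      dplyr::select(tidy(full_cva), "class", cva = "sensitivity"),
      by = "class")
    sens <- dplyr::rename(sens, syndrome = "class")
    sens <- sens[sens$syndrome != "unaffected", ]
    if (nrow(sens) >= 5) determinants_analysis(stats_tab, sens) else NULL
  })

  relatives <- stage("relatives", {
    if (!any(meta$diagnosis_status == "relative")) NULL else {
      unaff_cls <- tidy(full_hdrda)
      ua <- unaff_cls[unaff_cls$class == "unaffected", ]
      classify_relatives(shapes, meta, params = params, min_n = cfg$min_n,
                         unaffected_rate = ua$sensitivity,
                         unaffected_n = ua$n, severities = stats_tab)
    }
  })

  result <- structure(list(
    config = cfg, cohort = cohort, prep = prep, manova = manova_tab,
    dropped_syndromes = filt$dropped, two_group = two_group,
    hdrda_full = full_hdrda, hdrda_syndrome_only = syn_hdrda,
    cva_full = full_cva, cva_syndrome_only = syn_cva,
    syndrome_stats = stats_tab, determinants = dets, relatives = relatives
  ), class = "pipeline_result")

  if (!is.null(cfg$out_dir)) write_pipeline_report(result, cfg$out_dir)
  result
}

# MANOVA runs on pre-standardization shapes so age/sex terms carry signal
shapes_for_manova <- function(prep) {
  core <- prep$meta$diagnosis_status != "relative"
  X <- model_matrix_age_sex(prep$model, prep$meta$age, prep$meta$sex)
  raw <- prep$shapes +
    X %*% prep$model$coefficients -
    matrix(prep$model$consensus_shape, nrow(prep$shapes),
           ncol(prep$shapes), byrow = TRUE)
  raw[core, , drop = FALSE]
}

write_pipeline_report <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  wr(tibble::as_tibble(result$manova), "manova.csv")
  wr(result$prep$outliers, "outliers.csv")
  wr(tidy(result$two_group), "two_group_cva.csv")
  wr(tidy(result$hdrda_full), "hdrda_full_by_class.csv")
  wr(tidy(result$hdrda_syndrome_only), "hdrda_syndrome_only_by_class.csv")
  wr(tidy(result$cva_full), "cva_full_by_class.csv")
  wr(tidy(result$cva_syndrome_only), "cva_syndrome_only_by_class.csv")
  wr(result$syndrome_stats, "syndrome_stats.csv")
  post <- tibble::as_tibble(result$hdrda_full$posterior, rownames = "subject_id")
  wr(post, "hdrda_full_posteriors.csv")
  if (!is.null(result$determinants)) {
    wr(result$determinants$simple, "determinants_simple.csv")
    wr(result$determinants$combined, "determinants_combined.csv")
    wr(result$determinants$pca$scores, "determinants_pc1.csv")
  }
  if (!is.null(result$relatives)) {
    wr(result$relatives$by_relative, "relatives_by_relative.csv")
    wr(result$relatives$by_syndrome, "relatives_by_syndrome.csv")
  }
  cfg <- result$config
  cfg$cohort <- NULL
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  subjects analysed: ", nrow(x$prep$meta), "\n", sep = "")
  cat("  dropped syndromes (min-n): ",
      if (length(x$dropped_syndromes)) paste(x$dropped_syndromes,
                                             collapse = ", ") else "none",
      "\n", sep = "")
  g <- glance(x$hdrda_full)
  cat("  HDRDA (full sample) mean sensitivity: ",
      round(100 * g$mean_sensitivity, 1), "%\n", sep = "")
  invisible(x)
}
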