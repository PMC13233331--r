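#' Synthetic cohort generation
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' each patient is a bag of single-cell embedding vectors whose cell-type
#' composition is conditioned on the diagnostic class. Cell types are
#' represented by Gaussian clusters in embedding space (a stand-in for the
#' latent clusters a single-cell image encoder produces); a class recipe
#' draws a composition from a Dirichlet prior, with the myeloblast coordinate
#' overridden by an explicit latent "blast fraction" so that
#' probability-vs-blast-ratio relationships have a controllable ground truth.
#' Hemoglobin is drawn per class from a truncated normal on [3, 20] g/dL.
#'
#' @name synthetic_cohort
NULL

CELL_TYPE_ROLES <- c("myeloblast", "lymphocyte", "neutrophil", "monocyte",
                     "promyelocyte", "giant platelet")

# Mean cell-type composition per coarse class over the six canonical roles
# (myeloblast, lymphocyte, neutrophil, monocyte, promyelocyte, giant
# platelet). Each class occupies a distinct region of composition space:
# blast excess for acute leukemia, moderate blasts for MDS, monocytosis for
# MDS/MPN, giant platelets for MPN, lymphocytosis for lymphoma. Values are
# idealized signatures, not clinical differentials.
CLASS_COMPOSITIONS <- rbind(
  "acute leukemia"       = c(0.30, 0.20, 0.30, 0.10, 0.08, 0.02),
  "MDS"                  = c(0.10, 0.20, 0.54, 0.06, 0.06, 0.04),
  "MDS/MPN"              = c(0.08, 0.15, 0.42, 0.25, 0.05, 0.05),
  "MPN"                  = c(0.02, 0.12, 0.55, 0.05, 0.06, 0.20),
  "lymphoma"             = c(0.01, 0.70, 0.24, 0.03, 0.01, 0.01),
  "plasma cell neoplasm" = c(0.01, 0.50, 0.44, 0.02, 0.01, 0.02),
  "reactive changes"     = c(0.01, 0.40, 0.40, 0.14, 0.03, 0.02),
  "healthy"              = c(0.01, 0.28, 0.62, 0.06, 0.01, 0.02))

# Blast-fraction latent ranges: >= 20% blasts is the classical acute-leukemia
# criterion, so MDS stays strictly below 0.20.
BLAST_RANGES <- rbind(
  "acute leukemia"       = c(0.20, 0.90),
  "MDS"                  = c(0.02, 0.19),
  "MDS/MPN"              = c(0.02, 0.15),
  "MPN"                  = c(0.00, 0.05),
  "lymphoma"             = c(0.00, 0.02),
  "plasma cell neoplasm" = c(0.00, 0.02),
  "reactive changes"     = c(0.00, 0.02),
  "healthy"              = c(0.00, 0.02))

# Hemoglobin mean/sd in g/dL: anemia in acute leukemia and MDS, high values
# in MPN (polycythemia vera), near-normal for healthy/reactive.
HB_PARAMS <- rbind(
  "acute leukemia"       = c(8.6, 1.2),
  "MDS"                  = c(9.2, 1.2),
  "MDS/MPN"              = c(10.4, 1.3),
  "MPN"                  = c(15.0, 1.8),
  "lymphoma"             = c(12.3, 1.3),
  "plasma cell neoplasm" = c(10.3, 1.3),
  "reactive changes"     = c(13.0, 1.2),
  "healthy"              = c(14.3, 1.0))

# Released-test-set class frequencies, used as the default cohort prior.
DEFAULT_CLASS_COUNTS <- c(
  "acute leukemia" = 46, "MDS" = 38, "MDS/MPN" = 22, "MPN" = 48,
  "lymphoma" = 57, "plasma cell neoplasm" = 57, "reactive changes" = 42,
  "healthy" = 99)

#' Default cell-type profiles and class recipes
#'
#' Draws one embedding-space centroid per cell type (isotropic unit spread)
#' and builds one recipe per coarse class. Centroids are random directions
#' scaled by `separation`, so typical pairwise centroid distance grows
#' linearly with `separation`; `separation = 0` collapses all cell types onto
#' the origin, a null-signal negative control.
#'
#' @param n_cell_types number of cell types (>= 4). The first six are the
#'   canonical roles myeloblast, lymphocyte, neutrophil, monocyte,
#'   promyelocyte, giant platelet; extras are uninformative background types.
#' @param embedding_dim dimensionality of the cell embedding space.
#' @param separation nonnegative scale of centroid distances (units of the
#'   within-type spread, which is 1).
#' @param seed integer seed; profiles are a pure function of the arguments.
#' @param concentration Dirichlet precision of the per-patient composition
#'   draw (larger = compositions closer to the class mean).
#' @return A list with `profiles` (list of cell-type profiles: `name`,
#'   `mean_vector`, `spread`) and `recipes` (named list of class recipes:
#'   `coarse_class`, `composition_concentration`, `blast_fraction_range`,
#'   `hemoglobin_mean`, `hemoglobin_sd`).
#' @export
default_recipes <- function(n_cell_types = 6L, embedding_dim = 768L,
                            separation = 5, seed = 1L,
                            concentration = 60) {
  stopifnot(n_cell_types >= 4L, embedding_dim >= 2L, separation >= 0,
            concentration > 0)
  type_names <- if (n_cell_types <= length(CELL_TYPE_ROLES)) {
    CELL_TYPE_ROLES[seq_len(n_cell_types)]
  } else {
    c(CELL_TYPE_ROLES,
      paste0("background-", seq_len(n_cell_types - length(CELL_TYPE_ROLES))))
  }
  profiles <- with_seed(seed, {
    lapply(type_names, function(nm) {
      z <- stats::rnorm(embedding_dim)
      u <- z / sqrt(sum(z^2))
      list(name = nm, mean_vector = separation * u, spread = 1)
    })
  })
  names(profiles) <- type_names

  recipes <- lapply(rownames(CLASS_COMPOSITIONS), function(cls) {
    comp <- CLASS_COMPOSITIONS[cls, ]
    names(comp) <- CELL_TYPE_ROLES
    comp <- comp[intersect(CELL_TYPE_ROLES, type_names)]
    extras <- setdiff(type_names, names(comp))
    if (length(extras)) comp <- c(comp, stats::setNames(
      rep(0.01, length(extras)), extras))
    comp <- comp[type_names] / sum(comp[type_names])
    list(coarse_class = cls,
         composition_concentration = comp * concentration,
         blast_fraction_range = unname(BLAST_RANGES[cls, ]),
         hemoglobin_mean = unname(HB_PARAMS[cls, 1L]),
         hemoglobin_sd = unname(HB_PARAMS[cls, 2L]))
  })
  names(recipes) <- rownames(CLASS_COMPOSITIONS)
  list(profiles = profiles, recipes = recipes)
}

#' Generate one patient bag from a class recipe
#'
#' Composition is drawn from `Dirichlet(composition_concentration)`; the
#' myeloblast coordinate is then overridden by a uniform draw from
#' `blast_fraction_range` and the vector renormalized. Cell types are drawn
#' multinomially, each cell vector is its type centroid plus isotropic
#' Gaussian noise, and hemoglobin is `Normal(mean, sd)` truncated to
#' [3, 20] g/dL.
#'
#' @param recipe a class recipe (see [default_recipes()]).
#' @param profiles list of cell-type profiles.
#' @param n_cells number of cells in the bag (>= 1).
#' @param seed integer seed.
#' @param patient_id identifier stored in the bag.
#' @return A list with `bag` (a `cell_bag`: `patient_id`, `embeddings` matrix
#'   of `n_cells` rows, `cell_types` tags), `cell_type_counts`,
#'   `hemoglobin_measured`, and `blast_fraction_target` (the latent draw).
#' @export
generate_bag <- function(recipe, profiles, n_cells, seed,
                         patient_id = "patient") {
  stopifnot(n_cells >= 1L)
  if (length(profiles) == 0L) stop("empty profile list", call. = FALSE)
  alpha <- recipe$composition_concentration
  stopifnot(all(alpha > 0), length(alpha) == length(profiles))
  type_names <- names(profiles)
  emb_dim <- length(profiles[[1L]]$mean_vector)

  with_seed(seed, {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    w <- g / sum(g)
    names(w) <- type_names
    lo <- recipe$blast_fraction_range[1L]
    hi <- recipe$blast_fraction_range[2L]
    u <- stats::runif(1L, lo, hi)
    blast_idx <- match("myeloblast", type_names)
    if (!is.na(blast_idx)) {
      rest <- sum(w[-blast_idx])
      w[-blast_idx] <- if (rest > 0) w[-blast_idx] * (1 - u) / rest else
        (1 - u) / (length(w) - 1L)
      w[blast_idx] <- u
    }
    counts <- as.vector(stats::rmultinom(1L, n_cells, w))
    names(counts) <- type_names

    types <- rep(type_names, counts)
    x <- matrix(stats::rnorm(n_cells * emb_dim), n_cells, emb_dim)
    centroids <- t(vapply(profiles, `[[`, numeric(emb_dim), "mean_vector"))
    spreads <- vapply(profiles, `[[`, numeric(1L), "spread")
    ord <- sample.int(n_cells)
    types <- types[ord]
    ti <- match(types, type_names)
    x <- x * spreads[ti] + centroids[ti, , drop = FALSE]

    hb <- if (recipe$hemoglobin_sd == 0) recipe$hemoglobin_mean else {
      v <- stats::rnorm(1L, recipe$hemoglobin_mean, recipe$hemoglobin_sd)
      while (v < 3 || v > 20)
        v <- stats::rnorm(1L, recipe$hemoglobin_mean, recipe$hemoglobin_sd)
      v
    }
    hb <- min(max(hb, 3), 20)

    bag <- structure(list(patient_id = patient_id, embeddings = x,
                          cell_types = types), class = "cell_bag")
    list(bag = bag, cell_type_counts = counts, hemoglobin_measured = hb,
         blast_fraction_target = u)
  })
}

#' Generate a synthetic cohort
#'
#' Draws a diagnostic class per patient from `class_priors`, then a bag per
#' patient via [generate_bag()]. The default priors mirror a 409-patient
#' laboratory test-set composition (46 acute leukemia, 38 MDS, 22 MDS/MPN,
#' 48 MPN, 57 lymphoma, 57 plasma cell neoplasm, 42 reactive changes,
#' 99 healthy). Detailed classes are sampled uniformly within each coarse
#' class from the hierarchy.
#'
#' @param n_patients number of patients (>= 8).
#' @param class_priors probability vector over the 8 coarse classes in
#'   hierarchy order (must sum to 1 within 1e-9). Defaults to the released
#'   test-set composition.
#' @param n_cells cells per bag.
#' @param seed integer seed; the cohort is a pure function of its arguments.
#' @param recipes output of [default_recipes()] (or compatible); defaults to
#'   `default_recipes(embedding_dim = embedding_dim, separation = separation)`.
#' @param embedding_dim,separation forwarded to [default_recipes()] when
#'   `recipes` is not supplied.
#' @param hierarchy a `label_hierarchy`; defaults to [default_hierarchy()].
#' @return A list with `manifest` (data frame: patient_id, detailed_class,
#'   coarse_class, malignant, hemoglobin, blast fraction target, empirical
#'   blast/lymphocyte ratios, per-type counts, fold_id = NA) and `bags`
#'   (list of `cell_bag` keyed by patient_id).
#' @export
generate_cohort <- function(n_patients, class_priors = NULL, n_cells = 500L,
                            seed = 1L, recipes = NULL, embedding_dim = 768L,
                            separation = 5, hierarchy = default_hierarchy()) {
  stopifnot(n_patients >= 8L)
  if (is.null(class_priors))
    class_priors <- DEFAULT_CLASS_COUNTS / sum(DEFAULT_CLASS_COUNTS)
  stopifnot(length(class_priors) == 8L)
  if (abs(sum(class_priors) - 1) > 1e-9)
    stop("class priors must sum to 1 (got ", sum(class_priors), ")",
         call. = FALSE)
  if (is.null(recipes))
    recipes <- default_recipes(embedding_dim = embedding_dim,
                               separation = separation,
                               seed = derive_seed(seed, 0L))
  classes <- hierarchy$coarse_classes
  stopifnot(all(names(recipes$recipes) %in% classes))

  draws <- with_seed(derive_seed(seed, 1L), {
    cls <- sample(classes, n_patients, replace = TRUE, prob = class_priors)
    det <- vapply(cls, function(cc) {
      cands <- names(hierarchy$detailed_to_coarse)[
        hierarchy$detailed_to_coarse == cc]
      if (length(cands) == 1L) cands else sample(cands, 1L)
    }, character(1L))
    list(cls = cls, det = det)
  })

  ids <- sprintf("P%04d", seq_len(n_patients))
  bags <- vector("list", n_patients)
  rows <- vector("list", n_patients)
  type_names <- names(recipes$profiles)
  for (i in seq_len(n_patients)) {
    cc <- draws$cls[i]
    g <- generate_bag(recipes$recipes[[cc]], recipes$profiles, n_cells,
                      seed = derive_seed(seed, i + 1L), patient_id = ids[i])
    bags[[i]] <- g$bag
    counts <- g$cell_type_counts
    rows[[i]] <- data.frame(
      patient_id = ids[i],
      detailed_class = draws$det[i],
      coarse_class = cc,
      malignant = hierarchy$malignant_flags[[cc]],
      hemoglobin = g$hemoglobin_measured,
      blast_fraction_target = g$blast_fraction_target,
      blast_ratio = (if ("myeloblast" %in% type_names)
        counts[["myeloblast"]] else 0) / n_cells,
      lymphocyte_ratio = (if ("lymphocyte" %in% type_names)
        counts[["lymphocyte"]] else 0) / n_cells,
      n_cells = n_cells,
      fold_id = NA_integer_,
      check.names = FALSE)
    for (tn in type_names)
      rows[[i]][[paste0("count_", gsub("[ /]", "_", tn))]] <-
        unname(counts[tn])
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  names(bags) <- ids
  list(manifest = manifest, bags = bags)
}

#' @export
print.cell_bag <- function(x, ...) {
  cat("<cell_bag> patient", x$patient_id, "-", nrow(x$embeddings), "cells x",
      ncol(x$embeddings), "dims\n")
  if (!is.null(x$cell_types)) {
    tab <- sort(table(x$cell_types), decreasing = TRUE)
    cat("  tags:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}
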