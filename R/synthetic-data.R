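# Synthetic generators with the statistical structure the experiments assume:
# (a) mixture-of-Gaussians vector sets with controllable cluster separation,
# (b) image sets where instances are noisy "glomerulus" ellipses and lesion
#     positives additionally carry a crescent-shaped arc hugging the ellipse
#     boundary, with per-institution brightness/tint shifts emulating stain
#     and scanner differences across cohorts,
# (c) case-level binary sets where positive cases draw instances with an
#     elevated motif prevalence.

#' Specification for mixture-of-Gaussians vector sets
#'
#' @param k Clusters per set.
#' @param dim Vector dimension.
#' @param separation Cluster-mean separation: means are drawn on a sphere of
#'   radius `separation * sd` (i.e. the separation is stated in units of the
#'   within-cluster standard deviation).
#' @param sd Within-cluster (isotropic) standard deviation.
#' @param points_range Inclusive range for the number of points per set.
#' @param n_sets Number of sets.
#' @param seed RNG seed.
#' @return A `mixture_set_spec` object.
#' @export
mixture_set_spec <- function(k = 3L, dim = 8L, separation = 10, sd = 1,
                             points_range = c(40L, 80L), n_sets = 20L,
                             seed = 1L) {
  if (separation <= 0) stop("separation must be positive")
  if (k < 1) stop("k must be >= 1")
  structure(list(k = as.integer(k), dim = as.integer(dim),
                 separation = separation, sd = sd,
                 points_range = as.integer(points_range),
                 n_sets = as.integer(n_sets), seed = as.integer(seed)),
            class = "mixture_set_spec")
}

#' Generate mixture-of-Gaussians sets with ground-truth assignments
#'
#' Each set draws k cluster means uniformly on a sphere of radius
#' `separation * sd`, then scatters points isotropically around them; the
#' true assignments are returned for clustering scores (e.g. adjusted Rand
#' index against the soft K-means cascade).
#'
#' @param spec A [mixture_set_spec()].
#' @return List of sets, each with `X` (points x dim), `z` (true cluster per
#'   point) and `means` (k x dim).
#' @export
gen_mixture_sets <- function(spec) {
  stopifnot(inherits(spec, "mixture_set_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_sets), function(s) {
      dirs <- matrix(stats::rnorm(spec$k * spec$dim), spec$k)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      means <- dirs * spec$separation * spec$sd
      n <- if (spec$points_range[1] == spec$points_range[2]) {
        spec$points_range[1]
      } else {
        sample(seq(spec$points_range[1], spec$points_range[2]), 1L)
      }
      z <- sample.int(spec$k, n, replace = TRUE)
      X <- means[z, , drop = FALSE] +
        matrix(stats::rnorm(n * spec$dim, sd = spec$sd), n)
      list(X = X, z = z, means = means)
    })
  })
}

#' Specification for planted lesion-motif image sets
#'
#' Instances are noisy ellipse-on-background images; a positive instance
#' additionally carries a crescent-shaped annular arc (subtending 90-180
#' degrees) hugging the ellipse boundary at the stated contrast. Cases are
#' assigned to cohorts that emulate institutions: each cohort adds a global
#' brightness offset plus a mild per-channel tint, standing in for stain and
#' scanner differences.
#'
#' @param image_size Side length in pixels (square images).
#' @param contrast Additive intensity of the crescent motif; must exceed
#'   `noise_sd` for a separable task, and 0 gives the no-signal null.
#' @param noise_sd Pixel noise standard deviation.
#' @param institution_shift Per-cohort brightness offsets (length = number of
#'   cohorts, at least 2 to emulate multi-institution stain variation).
#' @param tint_strength Magnitude of the per-cohort channel tint.
#' @param n_cases Number of cases (groups).
#' @param n_neg_per_case Negative instances generated per case (the positive
#'   is added on top for the one-positive task).
#' @param channels Image channels (3 = RGB).
#' @param p_pos,p_neg Motif prevalence among instances of positive/negative
#'   cases (binary task only).
#' @param seed RNG seed.
#' @return A `lesion_image_spec` object.
#' @export
lesion_image_spec <- function(image_size = 64L, contrast = 0.6,
                              noise_sd = 0.05,
                              institution_shift = c(0, 0.08, -0.06),
                              tint_strength = 0.03, n_cases = 200L,
                              n_neg_per_case = 7L, channels = 3L,
                              p_pos = 0.6, p_neg = 0.05, seed = 1L) {
  if (contrast < 0) stop("contrast must be >= 0")
  if (length(institution_shift) < 2) {
    stop("need at least 2 cohorts (institution_shift entries)")
  }
  structure(list(image_size = as.integer(image_size), contrast = contrast,
                 noise_sd = noise_sd, institution_shift = institution_shift,
                 tint_strength = tint_strength, n_cases = as.integer(n_cases),
                 n_neg_per_case = as.integer(n_neg_per_case),
                 channels = as.integer(channels), p_pos = p_pos,
                 p_neg = p_neg, seed = as.integer(seed)),
            class = "lesion_image_spec")
}

# one synthetic glomerulus crop; draws from the current RNG stream
draw_lesion_instance <- function(spec, positive, shift, tint) {
  s <- spec$image_size
  cx <- s / 2 + stats::runif(1, -2, 2)
  cy <- s / 2 + stats::runif(1, -2, 2)
  a <- stats::runif(1, 0.28, 0.38) * s
  b <- stats::runif(1, 0.28, 0.38) * s
  xs <- matrix(seq_len(s), s, s)
  ys <- matrix(seq_len(s), s, s, byrow = TRUE)
  u <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
  rho <- sqrt(u)
  base <- 0.25 + 0.30 * (u <= 1) # background 0.25, tuft 0.55
  chan_gain <- if (spec$channels == 3) c(1.0, 0.85, 1.05) else rep(1, spec$channels)
  img <- array(rep(base, spec$channels) *
                 rep(chan_gain, each = s * s), c(s, s, spec$channels))
  if (positive && spec$contrast > 0) {
    span <- stats::runif(1, pi / 2, pi)
    th0 <- stats::runif(1, 0, 2 * pi)
    ang <- atan2(ys - cy, xs - cx) - th0
    ang <- ang %% (2 * pi)
    cres <- rho >= 0.72 & rho <= 1.02 & ang <= span
    cres_gain <- if (spec$channels == 3) c(1.0, 0.7, 0.85) else rep(1, spec$channels)
    img <- img + array(rep(cres * spec$contrast, spec$channels) *
                         rep(cres_gain, each = s * s),
                       c(s, s, spec$channels))
  }
  img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
  img <- img + shift + rep(tint, each = s * s)
  pmin(pmax(img, 0), 1)
}

#' Generate planted lesion-motif image sets
#'
#' For `task = "one_positive"`: every case (group) gets `n_neg_per_case`
#' motif-free instances and one motif-carrying instance; one set per case is
#' built with [build_one_positive_sets()], so each target is one-hot. For
#' `task = "binary"`: half the cases are positive; their instances carry the
#' motif with probability `p_pos` (vs `p_neg` for negative cases) and one set
#' per case is built with [build_binary_sets()] carrying the case label.
#'
#' @param spec A [lesion_image_spec()].
#' @param task `"one_positive"` or `"binary"`.
#' @param sets_per_case How many Monte Carlo sets to draw per case.
#' @return List with `images` (named list of H x W x C arrays), `manifest`
#'   (instance_id, group_id, cohort, label, and label_case for the binary
#'   task) and `sets` (list of `built_set`s).
#' @export
gen_lesion_image_sets <- function(spec, task = c("one_positive", "binary"),
                                  sets_per_case = 1L) {
  stopifnot(inherits(spec, "lesion_image_spec"))
  task <- match.arg(task)
  with_seed(spec$seed, {
    n_coh <- length(spec$institution_shift)
    tints <- lapply(seq_len(n_coh), function(i) {
      stats::runif(spec$channels, -spec$tint_strength, spec$tint_strength)
    })
    images <- list()
    rows <- list()
    for (cs in seq_len(spec$n_cases)) {
      coh <- ((cs - 1) %% n_coh) + 1L
      gid <- sprintf("case%04d", cs)
      case_lab <- if (task == "binary") as.integer(cs %% 2 == 0) else NA_integer_
      n_inst <- spec$n_neg_per_case + (task == "one_positive")
      pos_flags <- if (task == "one_positive") {
        c(TRUE, rep(FALSE, spec$n_neg_per_case))
      } else {
        stats::runif(n_inst) < (if (case_lab == 1) spec$p_pos else spec$p_neg)
      }
      for (i in seq_len(n_inst)) {
        iid <- sprintf("%s_g%02d", gid, i)
        images[[iid]] <- draw_lesion_instance(spec, pos_flags[i],
                                              spec$institution_shift[coh],
                                              tints[[coh]])
        rows[[length(rows) + 1]] <- data.frame(
          instance_id = iid, group_id = gid,
          cohort = sprintf("institution%d", coh),
          label = as.integer(pos_flags[i]), label_case = case_lab)
      }
    }
    manifest <- do.call(rbind, rows)
    if (task == "one_positive") manifest$label_case <- NULL
    groups <- rep(sprintf("case%04d", seq_len(spec$n_cases)),
                  each = sets_per_case)
    sets <- if (task == "one_positive") {
      build_one_positive_sets(manifest, length(groups),
                              seed = spec$seed + 1L, groups = groups)
    } else {
      build_binary_sets(manifest, length(groups), seed = spec$seed + 1L,
                        groups = groups)
    }
    list(images = images, manifest = manifest, sets = sets, spec = spec,
         task = task)
  })
}

#' Materialise built sets into model-ready inputs
#'
#' Resolves each built set's members against the generated images (applying
#' the recorded augmentation seed to augmented copies) or against a matrix of
#' precomputed embeddings, yielding the `list(x, y)` format consumed by
#' [train()] and [evaluate()].
#'
#' @param sets List of `built_set`s.
#' @param data Output of [gen_lesion_image_sets()] (for images), or a matrix
#'   whose rows line up with the pool manifest (for vector instances).
#' @return List of sets with `x` and `y`.
#' @export
materialize_sets <- function(sets, data) {
  vector_mode <- is.matrix(data)
  lapply(sets, function(s) {
    x <- if (vector_mode) {
      data[s$member_idx, , drop = FALSE]
    } else {
      lapply(seq_along(s$member_idx), function(i) {
        img <- data$images[[data$manifest$instance_id[s$member_idx[i]]]]
        if (isTRUE(s$augmented[i])) {
          img <- augment_instance(img, seed = s$aug_seed[i])
        }
        img
      })
    }
    list(x = x, y = s$target, set_id = s$set_id, group_id = s$group_id)
  })
}

#' Write a generated lesion dataset to disk (PNG images + CSV manifest)
#'
#' @param data Output of [gen_lesion_image_sets()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_lesion_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data$manifest
  man$path <- file.path(dir, paste0(man$instance_id, ".png"))
  for (i in seq_len(nrow(man))) {
    png::writePNG(data$images[[man$instance_id[i]]], man$path[i])
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  if (!is.null(data$sets)) write_sets(data$sets, file.path(dir, "sets.jsonl"))
  invisible(dir)
}

#' Read a lesion dataset written by [write_lesion_dataset()]
#' @param dir Dataset directory.
#' @return List with `images`, `manifest` and (if present) `sets`.
#' @export
read_lesion_dataset <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  images <- lapply(manifest$path, png::readPNG)
  names(images) <- manifest$instance_id
  sets_path <- file.path(dir, "sets.jsonl")
  sets <- if (file.exists(sets_path)) read_sets(sets_path) else NULL
  list(images = images, manifest = manifest, sets = sets)
}
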