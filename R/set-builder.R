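# Construction of training/validation sets from an instance pool: Monte Carlo
# one-positive composition, case-level binary sets, online augmentation to
# fill short sets, group-aware k-fold splitting, and crop preprocessing.
# The instance pool is a manifest data frame with columns
#   instance_id, group_id, cohort, label   (plus label_case for set tasks,
#   and optionally path when images live on disk).

# sample n elements of x without the base-R scalar surprise
sample_vec <- function(x, n) x[sample.int(length(x), n)]

check_pool <- function(pool, need = c("instance_id", "group_id", "label")) {
  miss <- setdiff(need, names(pool))
  if (length(miss)) stop("pool manifest lacks columns: ", paste(miss, collapse = ", "))
  if (!all(pool$label %in% c(0, 1))) stop("lesion labels must be 0/1")
  invisible(pool)
}

new_built_set <- function(set_id, members, member_idx, target, group_id,
                          augmented, aug_source, aug_seed) {
  structure(list(set_id = set_id, members = members, member_idx = member_idx,
                 target = target, group_id = group_id, augmented = augmented,
                 aug_source = aug_source, aug_seed = aug_seed),
            class = "built_set")
}

# draw n_fill augmented copies of randomly chosen source instances
fill_with_augmented <- function(chosen_idx, pool, n_fill) {
  src <- sample_vec(rep(chosen_idx,
                        length.out = max(n_fill, length(chosen_idx))), n_fill)
  list(idx = src,
       ids = paste0(pool$instance_id[src], "#aug",
                    seq_len(n_fill)),
       seeds = sample.int(.Machine$integer.max %/% 2L, n_fill))
}

#' Build one-positive instance sets (lesion-detection task)
#'
#' Each set contains one lesion-positive instance and m negatives with m
#' drawn uniformly from `m_range`, giving total sizes in
#' `[m_range[1] + 1, m_range[2] + 1]` (the default range 3..7 yields sets of
#' 4..8). Negatives are sampled without replacement from the positive's group
#' (the per-WSI scheme) or from the whole pool when `same_group = FALSE`.
#' When a group holds fewer negatives than m, augmented copies of existing
#' negatives fill the set; they are flagged so evaluation can exclude them,
#' and carry their own augmentation seeds.
#'
#' @param pool Manifest data frame (see above); `label` marks the lesion.
#' @param n_sets Number of sets to draw.
#' @param m_range Inclusive range for the number of negatives per set.
#' @param seed RNG seed; the same (pool, n_sets, seed) reproduces identical
#'   membership lists.
#' @param same_group Restrict negatives to the positive's group.
#' @param groups Optional vector (length `n_sets`) prescribing which group
#'   each set is drawn from; defaults to uniform draws over eligible groups.
#' @return List of `built_set` objects; each target is one-hot over members.
#' @export
build_one_positive_sets <- function(pool, n_sets, m_range = c(3L, 7L),
                                    seed = 1L, same_group = TRUE,
                                    groups = NULL) {
  check_pool(pool)
  pos_groups <- unique(pool$group_id[pool$label == 1])
  eligible <- pos_groups[vapply(pos_groups, function(g) {
    sum(pool$group_id == g & pool$label == 0) >= 1 || !same_group
  }, logical(1))]
  if (length(eligible) == 0) {
    stop("no group holds both a positive instance and a negative to sample")
  }
  if (!is.null(groups) && length(groups) != n_sets) {
    stop("`groups` must have one entry per requested set")
  }
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      g <- if (is.null(groups)) sample_vec(eligible, 1L) else groups[s]
      pos_idx <- which(pool$group_id == g & pool$label == 1)
      p <- sample_vec(pos_idx, 1L)
      neg_idx <- if (same_group) {
        which(pool$group_id == g & pool$label == 0)
      } else {
        which(pool$label == 0)
      }
      m <- sample_vec(seq(m_range[1], m_range[2]), 1L)
      take <- min(m, length(neg_idx))
      if (take == 0) stop("no negatives available for group ", g)
      neg <- sample_vec(neg_idx, take)
      ids <- pool$instance_id[c(p, neg)]
      idx <- c(p, neg)
      augmented <- rep(FALSE, length(idx))
      aug_source <- rep(NA_integer_, length(idx))
      aug_seed <- rep(NA_integer_, length(idx))
      if (take < m) {
        fl <- fill_with_augmented(neg, pool, m - take)
        ids <- c(ids, fl$ids)
        idx <- c(idx, fl$idx)
        augmented <- c(augmented, rep(TRUE, m - take))
        aug_source <- c(aug_source, fl$idx)
        aug_seed <- c(aug_seed, fl$seeds)
      }
      ord <- sample.int(length(idx))
      target <- as.integer(seq_along(idx)[ord] == 1)
      new_built_set(sprintf("set%05d", s), ids[ord], idx[ord], target, g,
                    augmented[ord], aug_source[ord], aug_seed[ord])
    })
  })
}

#' Build case-level binary sets
#'
#' Each set draws m instances (m uniform on `m_range`, default 4..8) without
#' replacement from one case/group; the target is the case's binary label
#' (column `label_case`, constant within a group). Short cases are filled
#' with augmented copies.
#'
#' @inheritParams build_one_positive_sets
#' @param m_range Inclusive range for the set size.
#' @return List of `built_set` objects with scalar 0/1 targets.
#' @export
build_binary_sets <- function(pool, n_sets, m_range = c(4L, 8L), seed = 1L,
                              groups = NULL) {
  check_pool(pool, c("instance_id", "group_id", "label_case"))
  all_groups <- unique(pool$group_id)
  if (!is.null(groups) && length(groups) != n_sets) {
    stop("`groups` must have one entry per requested set")
  }
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      g <- if (is.null(groups)) sample_vec(all_groups, 1L) else groups[s]
      gi <- which(pool$group_id == g)
      lab <- unique(pool$label_case[gi])
      if (length(lab) != 1) stop("case label not constant within group ", g)
      m <- sample_vec(seq(m_range[1], m_range[2]), 1L)
      take <- min(m, length(gi))
      pick <- sample_vec(gi, take)
      ids <- pool$instance_id[pick]
      idx <- pick
      augmented <- rep(FALSE, take)
      aug_source <- rep(NA_integer_, take)
      aug_seed <- rep(NA_integer_, take)
      if (take < m) {
        fl <- fill_with_augmented(pick, pool, m - take)
        ids <- c(ids, fl$ids)
        idx <- c(idx, fl$idx)
        augmented <- c(augmented, rep(TRUE, m - take))
        aug_source <- c(aug_source, fl$idx)
        aug_seed <- c(aug_seed, fl$seeds)
      }
      ord <- sample.int(length(idx))
      new_built_set(sprintf("set%05d", s), ids[ord], idx[ord], as.integer(lab),
                    g, augmented[ord], aug_source[ord], aug_seed[ord])
    })
  })
}

#' Online augmentation of one instance image
#'
#' Random resized crop (area scale drawn from `crop_scale`), vertical flip
#' with probability 0.5, and rotation by an angle uniform on
#' `[-max_rotate, max_rotate]` degrees. Output size equals input size.
#'
#' @param image H x W (grayscale) or H x W x C array in `[0, 1]`.
#' @param seed Optional seed; fixed seed reproduces the output exactly.
#' @param crop_scale Range of the linear crop factor.
#' @param max_rotate Maximum absolute rotation in degrees.
#' @return Augmented array with the same dimensions.
#' @export
augment_instance <- function(image, seed = NULL, crop_scale = c(0.8, 1),
                             max_rotate = 30) {
  if (length(image) == 0) stop("empty image")
  run <- function() {
    d <- dim(image)
    gray <- length(d) == 2
    img <- EBImage::Image(image,
                          colormode = if (gray) "Grayscale" else "Color")
    h <- d[1]; w <- d[2]
    s <- stats::runif(1, crop_scale[1], crop_scale[2])
    ch <- max(2L, round(s * h)); cw <- max(2L, round(s * w))
    oy <- sample.int(h - ch + 1L, 1L); ox <- sample.int(w - cw + 1L, 1L)
    img <- if (gray) img[oy:(oy + ch - 1L), ox:(ox + cw - 1L)]
           else img[oy:(oy + ch - 1L), ox:(ox + cw - 1L), ]
    img <- EBImage::resize(img, w = h, h = w)
    if (stats::runif(1) < 0.5) img <- EBImage::flip(img)
    ang <- stats::runif(1, -max_rotate, max_rotate)
    img <- EBImage::rotate(img, ang, output.dim = c(h, w), bg.col = 0)
    out <- EBImage::imageData(img)
    pmin(pmax(out, 0), 1)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Group-aware k-fold split
#'
#' Partitions groups (whole-slide images / cases) into k validation folds so
#' that no group ever straddles training and validation within a fold and
#' every group is validated exactly once across folds. Groups are assigned
#' largest-first to the currently lightest fold, which keeps the instance
#' counts near the target train/validation fraction (about (k-1)/k vs 1/k).
#'
#' @param records Data frame with a `group_id` column (one row per instance).
#' @param k Number of folds.
#' @param seed Shuffling seed.
#' @return List of k folds, each with `fold`, `val_groups`, `train_groups`,
#'   `val_idx`, `train_idx` (row indices into `records`).
#' @export
group_kfold_split <- function(records, k = 5L, seed = 1L) {
  groups <- table(as.character(records$group_id))
  if (length(groups) < k) {
    stop("need at least k = ", k, " distinct groups, got ", length(groups))
  }
  gnames <- names(groups)
  ord <- with_seed(seed, sample.int(length(groups)))
  gnames <- gnames[ord]
  sizes <- as.integer(groups)[ord]
  o <- order(sizes, decreasing = TRUE)
  fold_of <- integer(length(gnames))
  load <- numeric(k)
  for (i in o) {
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  lapply(seq_len(k), function(f) {
    vg <- gnames[fold_of == f]
    vi <- which(as.character(records$group_id) %in% vg)
    list(fold = f, val_groups = vg, train_groups = setdiff(gnames, vg),
         val_idx = vi, train_idx = setdiff(seq_len(nrow(records)), vi))
  })
}

#' Mask, square-pad and resize a glomerular crop
#'
#' Sets pixels outside the mask to zero, zero-pads the shorter axis (centred)
#' to a square, and isotropically resizes to `out_size` x `out_size` — the
#' aspect ratio of the foreground is preserved (no stretch).
#'
#' @param image H x W or H x W x C array.
#' @param mask H x W binary matrix (1 = inside the glomerulus); `NULL` for no
#'   masking.
#' @param out_size Output side length (default 256).
#' @return `out_size` x `out_size` (x C) array.
#' @export
preprocess_crop <- function(image, mask = NULL, out_size = 256L) {
  d <- dim(image)
  gray <- length(d) == 2
  if (!is.null(mask)) {
    if (!identical(as.integer(dim(mask)[1:2]), as.integer(d[1:2]))) {
      stop("mask and image spatial dimensions differ")
    }
    image <- if (gray) image * mask else image * as.vector(mask)
  }
  h <- d[1]; w <- d[2]
  side <- max(h, w)
  canvas <- if (gray) array(0, c(side, side)) else array(0, c(side, side, d[3]))
  oy <- (side - h) %/% 2
  ox <- (side - w) %/% 2
  if (gray) {
    canvas[(oy + 1):(oy + h), (ox + 1):(ox + w)] <- image
  } else {
    canvas[(oy + 1):(oy + h), (ox + 1):(ox + w), ] <- image
  }
  img <- EBImage::Image(canvas, colormode = if (gray) "Grayscale" else "Color")
  out <- EBImage::imageData(EBImage::resize(img, w = out_size, h = out_size))
  pmin(pmax(out, 0), 1)
}

# ---------------------------------------------------------------------------
# Manifest and built-set persistence
# ---------------------------------------------------------------------------

#' Read / write an instance-pool manifest (CSV)
#' @param pool Manifest data frame.
#' @param path CSV file.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   data frame.
#' @export
write_manifest <- function(pool, path) {
  utils::write.csv(pool, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Persist built sets as JSON lines
#'
#' One JSON object per line with the set id, members, target, group and
#' augmentation provenance, so a built experiment is fully reproducible.
#'
#' @param sets List of `built_set`s.
#' @param path Output file.
#' @return `write_sets` returns `path` invisibly; `read_sets` the list.
#' @export
write_sets <- function(sets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sets) {
    writeLines(jsonlite::toJSON(unclass(s), auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_sets
#' @export
read_sets <- function(path) {
  lapply(readLines(path), function(l) {
    s <- jsonlite::fromJSON(l)
    s$aug_source <- as.integer(s$aug_source)
    s$aug_seed <- as.integer(s$aug_seed)
    structure(s, class = "built_set")
  })
}
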