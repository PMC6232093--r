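#' Define the set of region-of-interest classes
#'
#' Up to 8 region classes may be analyzed at once. The conventional colon
#' set is `mucosa`, `lymphoid_follicle`, `tumor`, `other_tissue` and
#' `background`; optional `*_bis` edge classes (e.g. `mucosa_bis`,
#' `tumor_bis`) mark tissue margins whose area counts toward density
#' denominators but whose cells are excluded from positive counts.
#'
#' @param classes ordered character vector of 2--8 unique class names.
#' @return a list of class `ROIClassSet`.
#' @export
roi_class_set <- function(classes = c("mucosa", "lymphoid_follicle", "tumor",
                                      "other_tissue", "background")) {
  if (anyDuplicated(classes)) stop("class names must be unique")
  if (length(classes) < 2L || length(classes) > 8L)
    stop(sprintf("between 2 and 8 ROI classes are supported, got %d",
                 length(classes)))
  structure(list(classes = classes), class = "ROIClassSet")
}

#' Parent class of a `*_bis` edge class (or the class itself)
#' @param cl character vector of class names.
#' @return character vector with any `_bis` suffix stripped.
#' @export
bis_parent <- function(cl) sub("_bis$", "", cl)

#' Is a class a `*_bis` edge-exclusion class?
#' @param cl character vector of class names.
#' @return logical vector.
#' @export
is_bis <- function(cl) grepl("_bis$", cl)

# feature columns used by the region classifier
roi_feature_cols <- function(layer) {
  base <- c("area", "compactness", "heterogeneity", "local_density")
  ch <- unlist(lapply(layer$channel_names,
                      function(nm) paste0(c("mean_", "sd_", "context_"), nm)))
  c(base, ch)
}

#' Train a region classifier from exemplar primitive objects
#'
#' Exemplars play the role of the representative areas an analyst marks on
#' a training slide. A seeded random forest is fit on the standardized
#' object feature vector (area, compactness, heterogeneity, local density,
#' per-channel mean and sd); a nearest-centroid fallback is available for
#' very small exemplar sets.
#'
#' @param layer an `ObjectLayer` with features computed.
#' @param exemplars data frame with columns `object_id`, `class`.
#' @param class_set a [roi_class_set()]; every exemplar class must belong
#'   to it, and every non-`bis` class must have at least one exemplar.
#' @param seed integer seed making training deterministic.
#' @param method `"rf"` (default) or `"centroid"`.
#' @param ntree forest size (default 200).
#' @return an `ROIClassifier`.
#' @export
train_classifier <- function(layer, exemplars, class_set, seed = 1L,
                             method = c("rf", "centroid"), ntree = 200L) {
  stopifnot(inherits(layer, "ObjectLayer"), inherits(class_set, "ROIClassSet"))
  method <- match.arg(method)
  if (is.null(layer$features)) stop("compute_features() must be run first")
  if (!all(c("object_id", "class") %in% names(exemplars)))
    stop("exemplars need columns 'object_id' and 'class'")
  if (!all(exemplars$class %in% class_set$classes))
    stop("exemplar class not in the class set")
  dup <- tapply(exemplars$class, exemplars$object_id,
                function(z) length(unique(z)))
  if (any(dup > 1L))
    stop("conflicting classes for the same exemplar object")
  need <- setdiff(class_set$classes[!is_bis(class_set$classes)], exemplars$class)
  if (length(need))
    stop(sprintf("no exemplars for class(es): %s", paste(need, collapse = ", ")))
  cols <- roi_feature_cols(layer)
  X <- as.matrix(layer$features[exemplars$object_id, cols, drop = FALSE])
  y <- factor(exemplars$class, levels = class_set$classes)
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-9)
  Xs <- scale(X, ctr, scl)
  fit <- if (method == "rf") {
    set.seed(seed)
    randomForest::randomForest(Xs, droplevels(y), ntree = ntree)
  } else {
    cents <- rowsum(Xs, as.character(y)) / as.vector(table(as.character(y)))
    list(centroids = cents)
  }
  cl <- structure(list(method = method, fit = fit, cols = cols,
                       center = ctr, scale = scl, class_set = class_set,
                       seed = seed),
                  class = "ROIClassifier")
  pred <- predict_objects(cl, Xs_ready = Xs)
  acc <- mean(pred == as.character(y))
  message(sprintf("region classifier trained on %d exemplars, %d classes; training accuracy %.1f%%",
                  nrow(exemplars), nlevels(droplevels(y)), 100 * acc))
  cl
}

# predict class names from an already-standardized feature matrix
predict_objects <- function(classifier, X = NULL, Xs_ready = NULL) {
  Xs <- if (is.null(Xs_ready)) scale(X, classifier$center, classifier$scale)
        else Xs_ready
  if (classifier$method == "rf") {
    as.character(predict(classifier$fit, Xs))
  } else {
    cents <- classifier$fit$centroids
    d <- as.matrix(stats::dist(rbind(Xs, cents)))
    d <- d[seq_len(nrow(Xs)), nrow(Xs) + seq_len(nrow(cents)), drop = FALSE]
    rownames(cents)[apply(d, 1, which.min)]
  }
}

#' Classify every primitive object and merge into ROI objects
#'
#' Each primitive object receives a class from the trained classifier;
#' touching primitives of the same class are merged (transitive closure of
#' same-class adjacency) into ROI objects.
#'
#' @param classifier an `ROIClassifier` from [train_classifier()].
#' @param layer an `ObjectLayer` with features computed, sharing the
#'   classifier's feature schema.
#' @return an `ROILabeling`.
#' @export
classify_objects <- function(classifier, layer) {
  stopifnot(inherits(classifier, "ROIClassifier"), inherits(layer, "ObjectLayer"))
  n <- n_objects(layer)
  if (n == 0L)
    return(roi_labeling(layer, character(0), character(0), classifier$class_set))
  if (!all(classifier$cols %in% names(layer$features)))
    stop("feature-schema mismatch between classifier and layer")
  X <- as.matrix(layer$features[, classifier$cols, drop = FALSE])
  set.seed(classifier$seed)
  cls <- predict_objects(classifier, X)
  roi_labeling(layer, cls, rep("trained", n), classifier$class_set)
}

# build an ROILabeling: merge touching same-class primitives into ROI objects
roi_labeling <- function(layer, primitive_class, provenance, class_set) {
  n <- length(primitive_class)
  if (n == 0L) {
    return(structure(list(primitive_class = character(0),
                          provenance = character(0),
                          roi_id = integer(0),
                          roi_table = data.frame(roi_id = integer(),
                                                 class = character(),
                                                 area_um2 = numeric(),
                                                 n_px = integer(),
                                                 provenance = character()),
                          class_set = class_set),
                     class = "ROILabeling"))
  }
  b <- layer$boundary
  e <- b[b$b > 0L & b$a < b$b, c("a", "b")]
  same <- primitive_class[e$a] == primitive_class[e$b]
  g <- igraph::graph_from_data_frame(
    e[same, , drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  roi_id <- as.integer(comp)
  npx <- layer$features$n_px
  roi_npx <- rowsum_by(as.numeric(npx), roi_id, max(roi_id))
  roi_class <- character(max(roi_id))
  roi_class[roi_id] <- primitive_class
  roi_prov <- vapply(split(provenance, roi_id), function(p) {
    if (any(p == "manual")) "manual"
    else if (any(startsWith(p, "reclassified"))) p[startsWith(p, "reclassified")][1]
    else p[1]
  }, character(1))
  keep <- which(roi_npx > 0)
  remap <- integer(max(roi_id)); remap[keep] <- seq_along(keep)
  structure(list(primitive_class = primitive_class,
                 provenance = provenance,
                 roi_id = remap[roi_id],
                 roi_table = data.frame(
                   roi_id = seq_along(keep),
                   class = roi_class[keep],
                   area_um2 = area_um2(roi_npx[keep], layer$pixel_size),
                   n_px = as.integer(roi_npx[keep]),
                   provenance = unname(roi_prov[as.character(keep)]),
                   stringsAsFactors = FALSE),
                 class_set = class_set),
            class = "ROILabeling")
}

#' @export
print.ROILabeling <- function(x, ...) {
  cat(sprintf("ROILabeling: %d ROI objects over %d primitives\n",
              nrow(x$roi_table), length(x$primitive_class)))
  print(table(x$roi_table$class))
  invisible(x)
}

#' Render an `ROILabeling` as a class `LabelMask`
#' @param layer the `ObjectLayer` the labeling was built on.
#' @param labeling an `ROILabeling`.
#' @return a `LabelMask` with one label per class (in class-set order).
#' @export
roi_mask <- function(layer, labeling) {
  cls <- labeling$class_set$classes
  code <- stats::setNames(seq_along(cls), cls)
  lab <- layer$labels
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- as.integer(code[labeling$primitive_class[lab[nz]]])
  label_mask(out, stats::setNames(cls, as.character(seq_along(cls))))
}

#' Define a conditional reclassification rule
#'
#' A rule relabels every ROI object of `source` whose feature satisfies the
#' condition into `target`, emulating the ordered "composer" corrections an
#' analyst configures after training (e.g. oversized false follicles become
#' tumor; mucosa near tumor becomes tumor).
#'
#' @param source,target distinct class names.
#' @param feature one of `"area"` (um^2), `"relative_border"` (fraction,
#'   needs `class_arg`), `"distance_to"` (um, needs `class_arg`),
#'   `"heterogeneity"`, `"local_density"` (blobs/mm^2).
#' @param op comparison: `"<"`, `"<="`, `">="` or `">"`.
#' @param threshold finite numeric threshold.
#' @param class_arg reference class for `relative_border` / `distance_to`.
#' @return a list of class `ReclassRule`.
#' @export
reclass_rule <- function(source, target, feature, op, threshold,
                         class_arg = NULL) {
  feature <- match.arg(feature, c("area", "relative_border", "distance_to",
                                  "heterogeneity", "local_density"))
  op <- match.arg(op, c("<", "<=", ">=", ">"))
  if (identical(source, target)) stop("source and target classes must differ")
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (feature %in% c("relative_border", "distance_to") && is.null(class_arg))
    stop(sprintf("feature '%s' needs a reference class", feature))
  structure(list(source = source, target = target, feature = feature,
                 op = op, threshold = threshold, class_arg = class_arg),
            class = "ReclassRule")
}

#' Per-ROI-object features used by reclassification rules
#'
#' @param layer an `ObjectLayer` with features computed.
#' @param labeling an `ROILabeling`.
#' @param distance_classes classes for which a `distance_to_<class>` column
#'   (um, boundary-to-nearest-pixel) is computed.
#' @return data frame aligned with `labeling$roi_table`: `area_um2`,
#'   `heterogeneity` and `local_density` (area-weighted member means),
#'   `relative_border_<class>` fractions and requested distances.
#' @export
roi_features <- function(layer, labeling, distance_classes = character()) {
  rt <- labeling$roi_table
  nR <- nrow(rt)
  rid <- labeling$roi_id
  npx <- layer$features$n_px
  wsum <- function(v) rowsum_by(v * npx, rid, nR) / rowsum_by(as.numeric(npx), rid, nR)
  out <- data.frame(roi_id = rt$roi_id, class = rt$class,
                    area_um2 = rt$area_um2,
                    heterogeneity = wsum(layer$features$heterogeneity),
                    local_density = wsum(layer$features$local_density))
  # roi-level relative border: aggregate primitive contacts across ROI borders
  b <- layer$boundary
  # map contact endpoints to ROI ids; 0 (mask border) stays 0. Indexing
  # must be done on the nonzero positions only: subscripting with a 0
  # drops the element and would shift everything after it.
  ra <- integer(nrow(b)); pa <- b$a > 0L; ra[pa] <- rid[b$a[pa]]
  rb <- integer(nrow(b)); pb <- b$b > 0L; rb[pb] <- rid[b$b[pb]]
  ext <- ra != rb                       # contacts across roi borders or mask edge
  tot <- rowsum_by(as.numeric(b$n[ext]), ra[ext], nR)
  for (cl in unique(rt$class)) {
    sel <- ext & rb > 0L
    sel[sel] <- rt$class[rb[sel]] == cl
    out[[paste0("relative_border_", cl)]] <-
      if (any(sel)) rowsum_by(as.numeric(b$n[sel]), ra[sel], nR) / pmax(tot, 1)
      else numeric(nR)
  }
  for (cl in distance_classes) {
    out[[paste0("distance_to_", cl)]] <- roi_distance_to(layer, labeling, cl)
  }
  out
}

# minimal distance (um) from each ROI object to the nearest pixel of a class
roi_distance_to <- function(layer, labeling, target_class) {
  lab <- layer$labels
  nR <- nrow(labeling$roi_table)
  nz <- lab > 0L
  cls_px <- matrix(FALSE, nrow(lab), ncol(lab))
  cls_px[nz] <- labeling$primitive_class[lab[nz]] == target_class
  if (!any(cls_px)) return(rep(Inf, nR))
  d <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(matrix(as.numeric(!cls_px), nrow(lab)))))
  idx <- which(nz)
  rid <- labeling$roi_id[lab[idx]]
  dmin <- rep(Inf, nR)
  agg <- tapply(d[idx], rid, min)
  dmin[as.integer(names(agg))] <- agg
  dmin * layer$pixel_size
}

# evaluate one rule: logical over roi_table rows
rule_matches <- function(rule, feats) {
  v <- switch(rule$feature,
              area = feats$area_um2,
              heterogeneity = feats$heterogeneity,
              local_density = feats$local_density,
              relative_border = {
                col <- paste0("relative_border_", rule$class_arg)
                if (col %in% names(feats)) feats[[col]] else numeric(nrow(feats))
              },
              distance_to = feats[[paste0("distance_to_", rule$class_arg)]])
  ok <- switch(rule$op, `<` = v < rule$threshold, `<=` = v <= rule$threshold,
               `>=` = v >= rule$threshold, `>` = v > rule$threshold)
  ok & feats$class == rule$source
}

#' Apply an ordered list of reclassification rules
#'
#' Rules run strictly in list order. Each rule relabels every current ROI
#' object of its source class whose condition holds; merging and feature
#' refresh happen after each rule, so later rules see the updated labels.
#' All rules are validated against the class set before any mutation.
#'
#' @param layer an `ObjectLayer` with features computed.
#' @param labeling an `ROILabeling`.
#' @param rules list of [reclass_rule()]s (possibly empty).
#' @return the updated `ROILabeling`, with provenance
#'   `reclassified_by_rule_<k>` on relabeled objects.
#' @export
apply_rules <- function(layer, labeling, rules) {
  stopifnot(inherits(labeling, "ROILabeling"))
  known <- labeling$class_set$classes
  for (r in rules) {
    bad <- setdiff(c(r$source, r$target, r$class_arg), known)
    if (length(bad))
      stop(sprintf("rule references unknown class(es): %s",
                   paste(bad, collapse = ", ")))
  }
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    dc <- if (r$feature == "distance_to") r$class_arg else character()
    feats <- roi_features(layer, labeling, distance_classes = dc)
    hit <- which(rule_matches(r, feats))
    if (length(hit)) {
      prim_hit <- labeling$roi_id %in% hit
      pc <- labeling$primitive_class
      pv <- labeling$provenance
      pc[prim_hit] <- r$target
      pv[prim_hit] <- sprintf("reclassified_by_rule_%d", k)
      labeling <- roi_labeling(layer, pc, pv, labeling$class_set)
    }
  }
  labeling
}

#' Regularize a labeling by neighbor-majority absorption
#'
#' Classic object-based island removal: a primitive object surrounded
#' mostly by a single *other* class is absorbed into it. Applied
#' iteratively, this erases isolated misclassified primitives and smooths
#' ragged region borders without moving class cores (a primitive whose own
#' class holds the border majority never flips).
#'
#' @param layer an `ObjectLayer` with boundary computed.
#' @param labeling an `ROILabeling`.
#' @param min_frac minimal relative-border fraction a foreign class must
#'   hold to absorb a primitive (default 0.5; values below 0.5 are refused
#'   since two classes could then tie).
#' @param passes maximal number of sweeps (default 3).
#' @return the regularized `ROILabeling` (provenance `regularized` on
#'   flipped primitives).
#' @export
regularize_labeling <- function(layer, labeling, min_frac = 0.5, passes = 3L) {
  stopifnot(inherits(layer, "ObjectLayer"), inherits(labeling, "ROILabeling"),
            min_frac >= 0.5, passes >= 1L)
  pc <- labeling$primitive_class
  pv <- labeling$provenance
  if (!length(pc)) return(labeling)
  for (p in seq_len(passes)) {
    rb <- relative_border(layer, pc)
    best <- max.col(rb, ties.method = "first")
    bestv <- rb[cbind(seq_along(pc), best)]
    flip <- bestv > min_frac & colnames(rb)[best] != pc
    if (!any(flip)) break
    pc[flip] <- colnames(rb)[best[flip]]
    pv[flip] <- "regularized"
  }
  roi_labeling(layer, pc, pv, labeling$class_set)
}

#' Programmatic manual correction of ROI objects
#'
#' The programmatic stand-in for the visual-check step: exactly the listed
#' ROI objects change class; merging is re-run and provenance set to
#' `manual`.
#'
#' @param layer an `ObjectLayer`.
#' @param labeling an `ROILabeling`.
#' @param edits data frame with columns `roi_object_id`, `new_class`.
#' @return the corrected `ROILabeling`.
#' @export
manual_correct <- function(layer, labeling, edits) {
  if (NROW(edits) == 0L) return(labeling)
  stopifnot(all(c("roi_object_id", "new_class") %in% names(edits)))
  if (!all(edits$roi_object_id %in% labeling$roi_table$roi_id))
    stop("unknown ROI object id in edits")
  if (!all(edits$new_class %in% labeling$class_set$classes))
    stop("unknown class in edits")
  pc <- labeling$primitive_class
  pv <- labeling$provenance
  for (i in seq_len(nrow(edits))) {
    prim <- labeling$roi_id == edits$roi_object_id[i]
    pc[prim] <- edits$new_class[i]
    pv[prim] <- "manual"
  }
  roi_labeling(layer, pc, pv, labeling$class_set)
}

#' Derive training exemplars from a ground-truth or annotation mask
#'
#' A primitive object becomes an exemplar of a class when at least
#' `min_overlap` of its pixels carry that class in the annotation mask —
#' the programmatic equivalent of marking representative areas.
#'
#' @param layer an `ObjectLayer`.
#' @param mask a `LabelMask` whose legend names region classes.
#' @param min_overlap majority fraction required (default 0.5).
#' @param per_class optional cap on exemplars per class (deterministic
#'   subsample under `seed`).
#' @param seed integer seed for the subsample.
#' @return data frame `object_id`, `class`.
#' @export
exemplars_from_mask <- function(layer, mask, min_overlap = 0.5,
                                per_class = NULL, seed = 1L) {
  stopifnot(inherits(layer, "ObjectLayer"), inherits(mask, "LabelMask"))
  lab <- layer$labels
  n <- n_objects(layer)
  idx <- which(lab > 0L)
  ids <- lab[idx]
  gt <- mask$labels[idx]
  best <- t(vapply(split(gt, ids), function(g) {
    tb <- table(g)
    i <- which.max(tb)
    c(as.integer(names(tb)[i]), as.integer(tb[i]), length(g))
  }, integer(3)))
  oid <- as.integer(rownames(best))
  frac <- best[, 2] / best[, 3]
  keep <- frac >= min_overlap & best[, 1] > 0L
  ex <- data.frame(object_id = oid[keep],
                   class = unname(mask$legend[as.character(best[keep, 1])]),
                   stringsAsFactors = FALSE)
  if (!is.null(per_class)) {
    set.seed(seed)
    ex <- do.call(rbind, lapply(split(ex, ex$class), function(d) {
      if (nrow(d) > per_class) d[sort(sample.int(nrow(d), per_class)), ] else d
    }))
    rownames(ex) <- NULL
  }
  ex
}

#' The default four-composer reclassification ruleset
#'
#' Mirrors the ordered corrections used on colon sections: (1) oversized
#' false lymphoid follicles become tumor; (2) false mucosa islands
#' enclosed by tumor become tumor (the contact-based reading of the
#' proximity correction — a naive distance rule would swallow the true
#' mucosa, which always touches the tumor); (3) mucosa bordered mostly by
#' other tissue becomes other tissue; (4) small spurious tumor fragments
#' become other tissue. All thresholds are configuration, not printed
#' constants; defaults suit desk-scale fields where true follicles stay
#' below ~1e4 um^2.
#'
#' @param follicle_max_area_um2 rule 1 area threshold (default 1e4 um^2).
#' @param tumor_border_frac rule 2 relative-border threshold (default 0.5).
#' @param other_border_frac rule 3 relative-border threshold (default 0.6).
#' @param tumor_min_area_um2 rule 4 area threshold (default 300 um^2).
#' @return list of four [reclass_rule()]s.
#' @export
default_ruleset <- function(follicle_max_area_um2 = 1e4,
                            tumor_border_frac = 0.5,
                            other_border_frac = 0.6,
                            tumor_min_area_um2 = 300) {
  list(
    reclass_rule("lymphoid_follicle", "tumor", "area", ">=", follicle_max_area_um2),
    reclass_rule("mucosa", "tumor", "relative_border", ">=", tumor_border_frac,
                 class_arg = "tumor"),
    reclass_rule("mucosa", "other_tissue", "relative_border", ">=",
                 other_border_frac, class_arg = "other_tissue"),
    reclass_rule("tumor", "other_tissue", "area", "<", tumor_min_area_um2)
  )
}

#' Read a rules file (YAML list of source/target/feature/op/threshold)
#' @param path YAML path; entries may include `class_arg`.
#' @return list of [reclass_rule()]s.
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r)
    reclass_rule(r$source, r$target, r$feature, r$op, r$threshold,
                 class_arg = r$class_arg))
}
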