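## Random-forest voxel classification from sparse manual labels. The
## foreground class is "wall including lumen": selecting the whole vessel
## cross-section gives the classifier strong edges to learn, and the
## wax-filled lumen (same density as background) is removed later by
## intensity refinement.

#' Sparse manual labels
#'
#' A table of labelled voxels: 0-based coordinates `(z, y, x)` plus an
#' integer class id. Classes default to background = 0 and vessel = 1
#' (airway or blood-vessel wall plus lumen).
#'
#' @param z,y,x integer 0-based voxel coordinates (`z` is the slice index).
#' @param class integer class ids.
#' @param classes named integer vector mapping class names to ids.
#' @return A `label_set` data frame.
#' @export
label_set <- function(z, y, x, class,
                      classes = c(background = 0L, vessel = 1L)) {
  df <- data.frame(z = as.integer(z), y = as.integer(y), x = as.integer(x),
                   class = as.integer(class))
  if (!all(df$class %in% classes))
    stop("labels reference classes not in `classes`")
  structure(df, classes = classes, class = c("label_set", "data.frame"))
}

#' Read labels from a plain-text table
#'
#' Expects a comma- or whitespace-separated table with columns
#' `z, y, x, class` (header optional).
#'
#' @param path file path.
#' @param classes see [label_set()].
#' @return A `label_set`.
#' @export
read_labels <- function(path, classes = c(background = 0L, vessel = 1L)) {
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = header, sep = sep)
  if (!header) names(df) <- c("z", "y", "x", "class")[seq_len(ncol(df))]
  label_set(df$z, df$y, df$x, df$class, classes = classes)
}

#' Write labels to a plain-text table
#' @param labels a `label_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(as.data.frame(labels)[, c("z", "y", "x", "class")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Labels from an annotation stack
#'
#' Converts a label volume (0 = unlabeled, 1..K = class 1..K mapped to ids
#' `classes[k]`) into a `label_set`.
#'
#' @param stack 3D integer array, geometry of the volume.
#' @param classes named class-id vector, in annotation order.
#' @return A `label_set`.
#' @export
labels_from_stack <- function(stack, classes = c(background = 0L, vessel = 1L)) {
  w <- which(stack != 0, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("annotation stack contains no labels")
  ann <- stack[w]
  label_set(w[, 1] - 1L, w[, 2] - 1L, w[, 3] - 1L,
            classes[ann], classes = classes)
}

#' Extract training samples at labelled voxels
#'
#' Computes the feature stack only on the slices that carry labels (two
#' annotated slices of a 2000-slice scan cost two slices of filtering, not
#' the whole volume) and returns one feature vector per labelled voxel.
#' Duplicate coordinates yield duplicate samples.
#'
#' @param volume a [ct_volume()] or 3D array.
#' @param labels a [label_set()].
#' @param spec a [feature_spec()].
#' @param intensity_range optional global range for entropy quantization.
#' @return list with `x` (samples x features matrix), `y` (factor of class
#'   names), `fingerprint`, and `slices_used`.
#' @export
extract_training_set <- function(volume, labels, spec,
                                 intensity_range = NULL) {
  volume <- as_volume(volume)
  d <- dim(volume$data)
  bad <- labels$z < 0 | labels$z >= d[1] | labels$y < 0 | labels$y >= d[2] |
         labels$x < 0 | labels$x >= d[3]
  if (any(bad))
    stop("label outside volume at entry ", which(bad)[1], ": (",
         paste(unlist(labels[which(bad)[1], c("z", "y", "x")]),
               collapse = ","), ")")
  classes <- attr(labels, "classes")
  zs <- sort(unique(labels$z))
  xs <- vector("list", length(zs))
  ys <- vector("list", length(zs))
  for (s in seq_along(zs)) {
    z <- zs[s]
    sl <- array(volume$data[z + 1L, , ], d[2:3])
    fs <- build_feature_stack(sl, spec, intensity_range = intensity_range)
    rows <- labels[labels$z == z, ]
    lin <- rows$y + 1L + d[2] * rows$x     # column-major (y fastest)
    xs[[s]] <- fs$values[lin, , drop = FALSE]
    ys[[s]] <- rows$class
  }
  y <- factor(names(classes)[match(unlist(ys), classes)],
              levels = names(classes))
  list(x = do.call(rbind, xs), y = y,
       fingerprint = spec_fingerprint(spec), slices_used = zs)
}

#' Train the random-forest voxel classifier
#'
#' Fits a probability forest on the labelled samples exactly as given (no
#' resampling; curated label sets are small and their balance is part of
#' the training design). Deterministic for fixed samples, tree count and
#' seed.
#'
#' @param samples result of [extract_training_set()].
#' @param n_trees number of trees (default 200).
#' @param seed RNG seed for the forest (default 17).
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @return A `ct_classifier` carrying the forest, class list, feature-spec
#'   fingerprint and per-class sample counts.
#' @export
train_classifier <- function(samples, n_trees = 200L, seed = 17L,
                             mtry = NULL) {
  if (n_trees < 1L) stop("`n_trees` must be >= 1")
  y <- droplevels(samples$y)
  if (nlevels(y) < 2L)
    stop("training requires samples from at least 2 classes")
  p <- ncol(samples$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  df <- data.frame(samples$x, check.names = FALSE)
  df$.class <- y
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, mtry = mtry, probability = TRUE,
    seed = seed, num.threads = 1, verbose = FALSE)
  structure(list(forest = forest, classes = levels(y),
                 fingerprint = samples$fingerprint,
                 n_per_class = table(y), n_trees = n_trees, seed = seed),
            class = "ct_classifier")
}

#' @export
print.ct_classifier <- function(x, ...) {
  cat(sprintf("<ct_classifier> %d trees, classes: %s; samples: %s\n",
              x$n_trees, paste(x$classes, collapse = ", "),
              paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class),
                    collapse = ", ")))
  invisible(x)
}

#' Save / load a trained classifier
#'
#' The model is persisted together with its feature-spec fingerprint, class
#' list and seed in one archive file.
#'
#' @param model a `ct_classifier`.
#' @param path archive file path.
#' @return `path` / the restored `ct_classifier`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ct_classifier")) stop("not a classifier archive: ", path)
  m
}

#' Per-class probabilities for a block
#'
#' @param block 2D slice or 3D block.
#' @param model a `ct_classifier`.
#' @param spec the [feature_spec()] used in training.
#' @param intensity_range optional global range for entropy quantization.
#' @return matrix (voxels x classes) of probabilities summing to 1 per row.
#' @export
predict_probs <- function(block, model, spec, intensity_range = NULL) {
  fs <- build_feature_stack(block, spec, intensity_range = intensity_range)
  if (!identical(fs$fingerprint, model$fingerprint))
    stop("feature spec fingerprint does not match the trained model")
  pred <- stats::predict(model$forest,
                         data = data.frame(fs$values, check.names = FALSE),
                         num.threads = 1, verbose = FALSE)
  pred$predictions
}

#' Foreground probability map for a block
#'
#' Probability = fraction of trees voting for the foreground class
#' (soft-voted over the probability forest); higher values mean a voxel is
#' more likely part of an airway or blood vessel (wall plus lumen).
#'
#' @inheritParams predict_probs
#' @param foreground name of the foreground class (default `"vessel"`).
#' @return array of foreground probabilities with the block's geometry.
#' @export
predict_block <- function(block, model, spec, intensity_range = NULL,
                          foreground = "vessel") {
  probs <- predict_probs(block, model, spec, intensity_range)
  if (!foreground %in% colnames(probs))
    stop("foreground class '", foreground, "' not in model classes")
  d <- dim(block)
  p <- probs[, foreground]
  if (length(d) == 2L) matrix(p, d[1], d[2])
  else aperm(array(p, c(d[2], d[3], d[1])), c(3, 1, 2))
}
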