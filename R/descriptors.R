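#' Fit a reaction descriptor model
#'
#' Builds the descriptor matrix of a training set of reactions: ISIDA-style
#' fragment counts on the CGR (linear paths of `min_atoms`-`max_atoms` atoms)
#' concatenated with the 17 condition descriptors (15 solvent descriptors,
#' 1/T, molar ratio). The fragment vocabulary is the union of fragments seen
#' in the training set, in lexicographic column order, followed by the fixed
#' condition block. All columns are standardized to zero mean and unit
#' variance (population standard deviation; constant columns map to zero).
#'
#' @param data a data frame with columns `reaction` (atom-mapped reaction
#'   SMILES), `temperature_K`, and either `solvent` (name) or the 15 explicit
#'   `solv_*` columns (in the order of [condition_names()]); optional
#'   `molar_ratio` (default 100) and `property`.
#' @param min_atoms,max_atoms fragment size bounds (default 2 and 4).
#' @param solvents solvent lookup table, default [solvent_table()].
#' @param standardize_y if `TRUE`, also store mean/sd of `property` so
#'   regressors can be trained on the standardized property and predictions
#'   rescaled (used for Gaussian-process models).
#' @return an object of class `reaction_descriptors` with the fitted
#'   vocabulary, standardization parameters, the standardized training block
#'   `$x` and the training property `$y` (if present).
#' @seealso [predict.reaction_descriptors()]
#' @export
reaction_descriptors <- function(data, min_atoms = 2L, max_atoms = 4L,
                                 solvents = solvent_table(),
                                 standardize_y = FALSE) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L, "reaction" %in% names(data))
  frs <- lapply(data$reaction, function(s) cached_fragments(s, min_atoms, max_atoms))
  vocab <- sort(unique(unlist(lapply(frs, names))))
  obj <- structure(list(
    vocab = vocab, min_atoms = min_atoms, max_atoms = max_atoms,
    solvents = solvents, columns = c(vocab, condition_names())
  ), class = "reaction_descriptors")
  raw <- assemble_block(obj, data, frs)
  obj$center <- colMeans(raw$x)
  sd_pop <- sqrt(colMeans(sweep(raw$x, 2L, obj$center)^2))
  obj$scale <- sd_pop
  obj$x <- standardize_block(raw$x, obj$center, obj$scale)
  rownames(obj$x) <- rownames(raw$x)
  if ("property" %in% names(data)) {
    obj$y <- data$property
    if (standardize_y) {
      obj$y_center <- mean(obj$y)
      obj$y_scale <- sqrt(mean((obj$y - obj$y_center)^2))
      if (obj$y_scale == 0) obj$y_scale <- 1
    }
  }
  obj
}

#' @export
print.reaction_descriptors <- function(x, ...) {
  cat(sprintf("<reaction_descriptors> %d training reactions, %d fragment columns + %d condition columns\n",
              nrow(x$x), length(x$vocab), length(condition_names())))
  invisible(x)
}

#' Transform reactions into the fitted descriptor space
#'
#' Restricts new reactions to the fitted fragment vocabulary, appends the
#' condition block, applies the training standardization, and reports, for
#' every reaction, the fragments present in its CGR but absent from the
#' training vocabulary (the input of Fragment Control).
#'
#' @param object a fitted [reaction_descriptors()] model.
#' @param newdata data frame in the same format as the training data.
#' @param ... unused.
#' @return list with `x` (standardized matrix over the fitted columns) and
#'   `unseen` (list of character vectors of unseen fragment strings per row).
#' @export
predict.reaction_descriptors <- function(object, newdata, ...) {
  if (nrow(newdata) == 0L)
    return(list(x = matrix(0, 0L, length(object$columns),
                           dimnames = list(NULL, object$columns)),
                unseen = list()))
  frs <- lapply(newdata$reaction,
                function(s) cached_fragments(s, object$min_atoms, object$max_atoms))
  raw <- assemble_block(object, newdata, frs)
  list(x = standardize_block(raw$x, object$center, object$scale),
       unseen = raw$unseen)
}

assemble_block <- function(object, data, frs) {
  n <- nrow(data)
  x <- matrix(0, n, length(object$columns),
              dimnames = list(data$id %||% seq_len(n), object$columns))
  unseen <- vector("list", n)
  explicit <- all(paste0("solv_", seq_len(15L)) %in% names(data))
  mr <- if ("molar_ratio" %in% names(data)) data$molar_ratio else rep(100, n)
  for (i in seq_len(n)) {
    f <- frs[[i]]
    hit <- match(names(f), object$vocab)
    unseen[[i]] <- names(f)[is.na(hit)]
    ok <- !is.na(hit)
    x[i, hit[ok]] <- f[ok]
    solv <- if (explicit)
      as.numeric(data[i, paste0("solv_", seq_len(15L))])
    else data$solvent[i]
    x[i, condition_names()] <- condition_vector(solv, data$temperature_K[i],
                                                mr[i], table = object$solvents)
  }
  list(x = x, unseen = unseen)
}

standardize_block <- function(x, center, scale) {
  out <- sweep(x, 2L, center)
  nz <- scale > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, scale[nz], "/")
  out[, !nz] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write the delimited reaction dataset format
#'
#' The dataset is a CSV/TSV table with one row per reaction and columns
#' `reaction` (atom-mapped reaction SMILES), `property`, `temperature_K`,
#' `solvent` (or 15 explicit `solv_*` columns) and optional `molar_ratio`.
#' Synthetic datasets carry a sidecar table of hidden flags (true type id,
#' planted-outlier flag) written next to the main file as `<path>.flags.csv`;
#' the sidecar is never consumed by fitted models.
#'
#' @param path file path; `write_dataset` writes `<path>` and, when the
#'   dataset has a `flags` attribute, `<path>.flags.csv`.
#' @param data dataset data frame (for `write_dataset`).
#' @param sep field separator, `","` by default.
#' @return `read_dataset`: the dataset data frame, with the sidecar (if found)
#'   attached as attribute `flags`.
#' @export
read_dataset <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("reaction", "property", "temperature_K")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("dataset is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  side <- paste0(path, ".flags.csv")
  if (file.exists(side))
    attr(d, "flags") <- utils::read.csv(side, stringsAsFactors = FALSE)
  d
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path, sep = ",") {
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = TRUE)
  fl <- attr(data, "flags")
  if (!is.null(fl))
    utils::write.csv(fl, paste0(path, ".flags.csv"), row.names = FALSE)
  invisible(path)
}
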