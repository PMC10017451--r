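#' Specification of a synthetic labeled expression dataset
#'
#' Describes the study conditions the generator emulates: a small number of
#' classes with imbalanced cell counts, sparse non-negative log-scale
#' expression, and a small planted set of class-discriminative genes among
#' many null genes. Defaults give three moderately imbalanced classes
#' (300/600/900 cells), 500 genes of which 10 are informative with a
#' 2.0 log-unit shift, a background mean of 1.5 with unit dispersion, and
#' 50% dropout, producing sparse values concentrated in roughly [0, 8].
#'
#' @param class_sizes positive integers, cells per class.
#' @param n_genes positive integer.
#' @param n_informative non-negative integer, number of planted
#'   discriminative genes (`<= n_genes`).
#' @param effect_size non-negative mean log-expression shift applied to an
#'   informative gene in the class it marks.
#' @param base_mean non-negative background mean on the log scale.
#' @param dispersion positive noise SD on the log scale.
#' @param dropout_rate probability in `[0, 1]` that a value is zeroed.
#' @param seed integer RNG seed.
#' @param class_names labels for the classes; defaults to the three
#'   prime-boost vaccination strategies.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(class_sizes = c(300L, 600L, 900L),
                       n_genes = 500L,
                       n_informative = 10L,
                       effect_size = 2.0,
                       base_mean = 1.5,
                       dispersion = 1.0,
                       dropout_rate = 0.5,
                       seed = 1L,
                       class_names = c("BNT-BNT", "ChAd-BNT", "ChAd-ChAd")) {
  if (length(class_sizes) < 2L) stopf("need at least two classes")
  if (any(class_sizes != round(class_sizes)) || any(class_sizes <= 0))
    stopf("class sizes must be positive integers")
  if (n_genes < 1L) stopf("n_genes must be positive")
  if (n_informative < 0L || n_informative > n_genes)
    stopf("n_informative must lie in [0, n_genes]")
  if (effect_size < 0) stopf("effect_size must be non-negative")
  if (dispersion <= 0) stopf("dispersion must be positive")
  if (dropout_rate < 0 || dropout_rate > 1)
    stopf("dropout_rate must lie in [0, 1]")
  if (length(class_names) != length(class_sizes))
    stopf("class_names must match class_sizes in length")
  if (anyDuplicated(class_names)) stopf("class names must be unique")
  structure(
    list(class_sizes = as.integer(class_sizes),
         n_genes = as.integer(n_genes),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, base_mean = base_mean,
         dispersion = dispersion, dropout_rate = dropout_rate,
         seed = as.integer(seed), class_names = as.character(class_names)),
    class = "synth_spec"
  )
}

#' Generate a labeled dataset with planted discriminative genes
#'
#' Values are drawn as `max(0, Normal(base_mean + shift, dispersion))` and
#' then zeroed with probability `dropout_rate`, yielding sparse non-negative
#' log-scale expression. Informative genes follow class-specific
#' up/neutral/down patterns: gene `j` is shifted by `+effect_size` in class
#' `((j - 1) mod L) + 1`, by `-effect_size` in the next class (cyclically),
#' and left at the background mean elsewhere, so the patterns differ across
#' classes and each planted gene separates at least one class pair. The
#' same spec (including its seed) always produces a bitwise-identical
#' dataset.
#'
#' @param spec a [synth_spec()].
#' @return a list with elements `dataset` (an [expr_dataset()]) and `truth`,
#'   where `truth` has `informative_genes` (character) and
#'   `class_mean_shifts` (matrix, informative genes x classes).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n_cells <- sum(spec$class_sizes)
  L <- length(spec$class_sizes)
  p <- spec$n_genes
  gene_ids <- sprintf("G%04d", seq_len(p))
  cell_ids <- sprintf("C%05d", seq_len(n_cells))
  labels <- factor(rep(spec$class_names, spec$class_sizes),
                   levels = spec$class_names)

  info_idx <- seq_len(spec$n_informative)
  shifts <- matrix(0, nrow = spec$n_informative, ncol = L,
                   dimnames = list(gene_ids[info_idx], spec$class_names))
  if (spec$n_informative > 0L) {
    up_class <- ((info_idx - 1L) %% L) + 1L
    down_class <- (info_idx %% L) + 1L
    shifts[cbind(seq_along(info_idx), up_class)] <- spec$effect_size
    shifts[cbind(seq_along(info_idx), down_class)] <- -spec$effect_size
  }

  values <- with_seed(spec$seed, {
    m <- matrix(stats::rnorm(n_cells * p, mean = spec$base_mean,
                             sd = spec$dispersion),
                nrow = n_cells, ncol = p)
    if (spec$n_informative > 0L) {
      class_idx <- as.integer(labels)
      for (j in seq_along(info_idx))
        m[, info_idx[j]] <- m[, info_idx[j]] + shifts[j, class_idx]
    }
    m[m < 0] <- 0
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(n_cells * p) < spec$dropout_rate,
                     nrow = n_cells)
      m[drop] <- 0
    }
    m
  })

  ds <- expr_dataset(values, gene_ids = gene_ids, cell_ids = cell_ids,
                     labels = labels)
  list(dataset = ds,
       truth = list(informative_genes = gene_ids[info_idx],
                    class_mean_shifts = shifts))
}
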