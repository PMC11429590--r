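# Reading, validation and descriptive summary of six-generation phenotype
# data (one phenotype value per individual, labelled by generation).

#' Construct a generation sample
#'
#' @param generation One of `"P1"`, `"P2"`, `"F1"`, `"F2"`, `"BC1P1"`,
#'   `"BC1P2"` (case-insensitive).
#' @param values Numeric vector of phenotype measurements (e.g. mg/100 g
#'   fresh weight); at least 2 finite values.
#' @param cross_id Text label for the cross.
#' @return Object of class `generation_sample`.
#' @export
generation_sample <- function(generation, values, cross_id = "") {
  gen <- toupper(trimws(generation))
  if (length(gen) != 1L || !gen %in% GENERATIONS) {
    stop("generation must be one of ", paste(GENERATIONS, collapse = ", "),
         call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("generation ", gen, ": need at least 2 values (variance undefined)",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("generation ", gen, ": all values must be finite", call. = FALSE)
  }
  structure(list(generation = gen, values = values, cross_id = cross_id),
            class = "generation_sample")
}

#' Construct a six-generation dataset
#'
#' @param samples List of [generation_sample()] objects covering each of the
#'   six generations exactly once.
#' @param cross_id Text label for the cross.
#' @return Object of class `six_gen_dataset`; element `samples` is a named
#'   list in canonical generation order.
#' @export
six_gen_dataset <- function(samples, cross_id = "") {
  gens <- vapply(samples, function(s) s$generation, character(1))
  if (anyDuplicated(gens)) {
    stop("duplicate generation(s): ",
         paste(unique(gens[duplicated(gens)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(GENERATIONS, gens)
  if (length(missing)) {
    stop("incomplete design: missing generation(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  names(samples) <- gens
  structure(list(cross_id = cross_id, samples = samples[GENERATIONS]),
            class = "six_gen_dataset")
}

#' @export
print.six_gen_dataset <- function(x, ...) {
  ns <- vapply(x$samples, function(s) length(s$values), integer(1))
  cat("Six-generation dataset", if (nzchar(x$cross_id)) paste0("(", x$cross_id, ")"),
      "\n  n:", paste(sprintf("%s=%d", names(ns), ns), collapse = ", "), "\n")
  invisible(x)
}

#' Read a six-generation phenotype CSV
#'
#' Expects a header with columns `generation` and `value`; generation labels
#' are matched case-insensitively against P1, P2, F1, F2, BC1P1, BC1P2. Row
#' order is preserved within each generation.
#'
#' @param path CSV file path.
#' @param cross_id Text label attached to the dataset.
#' @param sep Field separator (`","`; use `"\t"` for TSV).
#' @return A [six_gen_dataset()].
#' @export
read_dataset <- function(path, cross_id = "", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("generation", "value") %in% names(df))) {
    stop("CSV must have header columns 'generation' and 'value'", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(vals) & !is.na(df$value))
  if (length(bad)) {
    stop("non-numeric value in row ", bad[1], ": '", df$value[bad[1]], "'",
         call. = FALSE)
  }
  if (anyNA(vals)) {
    stop("missing value in row ", which(is.na(vals))[1], call. = FALSE)
  }
  gen <- toupper(trimws(df$generation))
  unknown <- setdiff(unique(gen), GENERATIONS)
  if (length(unknown)) {
    stop("unknown generation label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  present <- intersect(GENERATIONS, unique(gen))
  missing <- setdiff(GENERATIONS, present)
  if (length(missing)) {
    stop("incomplete design: missing generation(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  samples <- lapply(present, function(g) {
    generation_sample(g, vals[gen == g], cross_id = cross_id)
  })
  six_gen_dataset(samples, cross_id = cross_id)
}

#' Write a six-generation dataset as CSV
#'
#' Inverse of [read_dataset()]: columns `generation`, `value` and, when the
#' dataset carries a non-empty cross label, `cross`.
#'
#' @param dataset A [six_gen_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.six_gen_dataset <- function(x, ...) {
  df <- do.call(rbind, lapply(x$samples, function(s) {
    data.frame(generation = s$generation, value = s$values,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (nzchar(x$cross_id)) df$cross <- x$cross_id
  df
}

#' Descriptive summary of one generation sample
#'
#' Computes the descriptive layer used for six-generation data: n, range,
#' mean, standard deviation (n-1 denominator), variance, coefficient of
#' variation, and the sample-size-adjusted skewness and excess kurtosis
#' (the adjusted Fisher-Pearson `G1 = g1 * sqrt(n(n-1))/(n-2)` and the
#' bias-corrected excess kurtosis `G2 = ((n+1) g2 + 6)(n-1)/((n-2)(n-3))`,
#' the conventions of mainstream commercial statistics software). Kurtosis
#' requires n >= 4 and skewness n >= 3; for constant samples both are
#' undefined (`NA`).
#'
#' @param sample A [generation_sample()] or bare numeric vector (n >= 2).
#' @return A one-row data frame with columns `generation`, `n`, `min`,
#'   `max`, `mean`, `sd`, `variance`, `cv_percent`, `skewness`, `kurtosis`.
#' @export
summarize_generation <- function(sample) {
  if (inherits(sample, "generation_sample")) {
    gen <- sample$generation
    x <- sample$values
  } else {
    gen <- NA_character_
    x <- as.numeric(sample)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  mu <- mean(x)
  s <- stats::sd(x)
  if (mu == 0) stop("mean is zero: coefficient of variation undefined",
                    call. = FALSE)
  skw <- if (n >= 3L && s > 0) e1071::skewness(x, type = 2) else NA_real_
  krt <- if (n >= 4L && s > 0) e1071::kurtosis(x, type = 2) else NA_real_
  data.frame(generation = gen, n = n, min = min(x), max = max(x),
             mean = mu, sd = s, variance = s^2,
             cv_percent = 100 * s / mu,
             skewness = skw, kurtosis = krt,
             stringsAsFactors = FALSE)
}

#' Descriptive summary table for a six-generation dataset
#'
#' One [summarize_generation()] row per generation, in canonical order.
#'
#' @param dataset A [six_gen_dataset()].
#' @param digits Optional rounding for the reporting layer (`NULL` keeps
#'   full precision; tables in publications typically use 2).
#' @return Data frame with one row per generation.
#' @export
summarize_dataset <- function(dataset, digits = NULL) {
  stopifnot(inherits(dataset, "six_gen_dataset"))
  out <- do.call(rbind, lapply(dataset$samples, summarize_generation))
  rownames(out) <- NULL
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "n"
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean`, the scale-free spread measure used to compare
#' phenotypic variability across generations.
#'
#' @param mean,sd Mean and standard deviation (same units); `mean` must be
#'   non-zero.
#' @return CV in percent.
#' @examples
#' cv_percent(101.00, 20.27)
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) stop("mean is zero: CV undefined", call. = FALSE)
  100 * sd / mean
}
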