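#' Outcome classes
#'
#' The three-level outcome used throughout the package: no MAFLD, nondiabetic
#' MAFLD (obese and lean subtypes merged, both being BMI-defined), and
#' diabetic MAFLD. The order fixes the class indices 0, 1, 2.
#'
#' @return Character vector of the three class labels, in index order.
#' @export
mafld_classes <- function() {
  c("non_MAFLD", "nondiabetic_MAFLD", "diabetic_MAFLD")
}

#' Declare a cohort feature schema
#'
#' A schema names every feature, assigns it to one of the four groups --
#' demographics (`D`), clinical (`C`), lifestyle survey (`S_lif`), genetic
#' family history survey (`S_gen`) -- and declares its kind. A feature is
#' declared as the string `"numeric"` or as a character vector of at least
#' two categorical levels.
#'
#' @param D,C,S_lif,S_gen Named lists; each element is `"numeric"` or a
#'   character vector of levels (length >= 2).
#' @return An object of class `feature_schema` with elements `features`
#'   (data frame: `name`, `group`, `kind`) and `levels` (named list of level
#'   sets for categorical features).
#' @examples
#' sch <- feature_schema(
#'   D = list(age = "numeric", sex = c("female", "male")),
#'   C = list(bmi = "numeric"),
#'   S_lif = list(smoking = c("never", "former", "current")),
#'   S_gen = list(fh_diabetes = c("no", "yes"))
#' )
#' @export
feature_schema <- function(D = list(), C = list(), S_lif = list(),
                           S_gen = list()) {
  groups <- list(D = D, C = C, S_lif = S_lif, S_gen = S_gen)
  rows <- list()
  levels <- list()
  for (g in names(groups)) {
    spec <- groups[[g]]
    if (length(spec) && is.null(names(spec)))
      stop("features in group ", g, " must be named", call. = FALSE)
    for (nm in names(spec)) {
      v <- spec[[nm]]
      if (identical(v, "numeric")) {
        kind <- "numeric"
      } else if (is.character(v) && length(v) >= 2 && !anyDuplicated(v)) {
        kind <- "categorical"
        levels[[nm]] <- v
      } else {
        stop("feature '", nm, "' must be \"numeric\" or >=2 distinct levels",
             call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, group = g, kind = kind, stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, rows)
  if (is.null(features))
    stop("schema declares no features", call. = FALSE)
  if (anyDuplicated(features$name))
    stop("duplicate feature name across groups: ",
         features$name[duplicated(features$name)][1], call. = FALSE)
  structure(list(features = features, levels = levels),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  tab <- table(factor(x$features$group, c("D", "C", "S_lif", "S_gen")))
  cat("<feature_schema> ", nrow(x$features), " features (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Feature names of a schema, optionally restricted to groups
#' @param schema A [feature_schema()].
#' @param groups Character vector of group ids, default all.
#' @return Character vector of feature names in schema order.
#' @export
schema_features <- function(schema, groups = c("D", "C", "S_lif", "S_gen")) {
  stopifnot(inherits(schema, "feature_schema"))
  schema$features$name[schema$features$group %in% groups]
}

#' Default study-sized schema
#'
#' The schema used by the synthetic cohort generator, mirroring the study's
#' group sizes: 2 demographic (age, sex), 36 numeric clinical, 32 categorical
#' lifestyle (4 levels each), 42 categorical genetic family history (3 levels
#' each).
#'
#' @param n_clinical,n_lifestyle,n_genetic Group sizes.
#' @param lifestyle_levels,genetic_levels Number of coded levels per survey
#'   feature.
#' @return A [feature_schema()].
#' @export
default_schema <- function(n_clinical = 36, n_lifestyle = 32, n_genetic = 42,
                           lifestyle_levels = 4, genetic_levels = 3) {
  lev <- function(J) paste0("L", seq_len(J))
  pad <- function(prefix, n) sprintf("%s_%02d", prefix, seq_len(n))
  feature_schema(
    D = list(age = "numeric", sex = c("female", "male")),
    C = stats::setNames(rep(list("numeric"), n_clinical),
                        pad("clin", n_clinical)),
    S_lif = stats::setNames(rep(list(lev(lifestyle_levels)), n_lifestyle),
                            pad("lif", n_lifestyle)),
    S_gen = stats::setNames(rep(list(lev(genetic_levels)), n_genetic),
                            pad("gen", n_genetic))
  )
}

#' Construct a cohort table
#'
#' Bundles a feature data frame, the 3-class outcome and a missingness mask
#' into the container every downstream stage consumes. The mask is the single
#' source of truth for missingness; masked cells are `NA` in `data`.
#'
#' @param data Data frame whose columns are exactly the schema features, in
#'   schema order.
#' @param y Outcome: factor or character with levels among [mafld_classes()].
#' @param schema A [feature_schema()].
#' @param mask Logical matrix, `TRUE` = missing; default derived from `NA`
#'   cells of `data`.
#' @param allow_missing Groups whose features may hold missing values
#'   (default the two survey groups).
#' @return An object of class `cohort_table` with elements `data`, `y`
#'   (factor), `mask`, `schema`.
#' @export
cohort_table <- function(data, y, schema,
                         mask = NULL,
                         allow_missing = c("S_lif", "S_gen")) {
  stopifnot(inherits(schema, "feature_schema"))
  feats <- schema$features$name
  if (!identical(colnames(data), feats)) {
    extra <- setdiff(colnames(data), feats)
    if (length(extra))
      stop("unknown column not in schema: '", extra[1], "'", call. = FALSE)
    miss <- setdiff(feats, colnames(data))
    if (length(miss))
      stop("schema feature missing from data: '", miss[1], "'", call. = FALSE)
    data <- data[, feats, drop = FALSE]
  }
  n <- nrow(data)
  if (anyNA(y) || length(y) != n)
    stop("every row must carry a label", call. = FALSE)
  y <- factor(as.character(y), levels = mafld_classes())
  if (anyNA(y))
    stop("label not among declared outcome classes", call. = FALSE)
  # type columns and validate categorical levels
  for (i in seq_len(nrow(schema$features))) {
    nm <- schema$features$name[i]
    if (schema$features$kind[i] == "numeric") {
      data[[nm]] <- as.numeric(data[[nm]])
    } else {
      lv <- schema$levels[[nm]]
      vals <- as.character(data[[nm]])
      bad <- !is.na(vals) & !(vals %in% lv)
      if (any(bad))
        stop("undeclared level '", vals[bad][1], "' for categorical feature '",
             nm, "'", call. = FALSE)
      data[[nm]] <- factor(vals, levels = lv)
    }
  }
  if (is.null(mask)) {
    mask <- is.na(as.matrix(data))
  }
  mask <- matrix(as.logical(mask), n, length(feats),
                 dimnames = list(NULL, feats))
  forbidden <- schema$features$name[!(schema$features$group %in% allow_missing)]
  if (length(forbidden) && any(mask[, forbidden]))
    stop("missing values only allowed in groups: ",
         paste(allow_missing, collapse = ", "), call. = FALSE)
  for (nm in feats) data[[nm]][mask[, nm]] <- NA
  structure(list(data = data, y = y, mask = mask, schema = schema),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> n=", nrow(x$data), ", ", ncol(x$data), " features, ",
      "missing ", round(100 * mean(x$mask), 2), "% of cells\n", sep = "")
  print(table(x$y))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$data)

#' Subset a cohort table by row indices
#' @param table A [cohort_table()].
#' @param idx Integer row indices.
#' @return A `cohort_table` restricted to `idx`, order preserved.
#' @export
subset_cohort <- function(table, idx) {
  stopifnot(inherits(table, "cohort_table"))
  structure(list(data = table$data[idx, , drop = FALSE],
                 y = table$y[idx],
                 mask = table$mask[idx, , drop = FALSE],
                 schema = table$schema),
            class = "cohort_table")
}

#' Read a cohort table from delimited text
#'
#' The file must have a header with exactly the schema's feature names plus a
#' label column. Empty cells and the literal `NA` are read as missing.
#' Delimiter is inferred from the extension (`.tsv` = tab, otherwise comma).
#'
#' @param path File path.
#' @param schema A [feature_schema()].
#' @param label_col Name of the label column (default `"label"`).
#' @param allow_missing Passed to [cohort_table()].
#' @param quiet Suppress the row/column/missingness log message.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(path, schema, label_col = "label",
                        allow_missing = c("S_lif", "S_gen"), quiet = FALSE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"))
  if (!label_col %in% colnames(raw))
    stop("missing label column '", label_col, "'", call. = FALSE)
  y <- raw[[label_col]]
  if (anyNA(y))
    stop("missing label in row ", which(is.na(y))[1], call. = FALSE)
  dat <- raw[, setdiff(colnames(raw), label_col), drop = FALSE]
  extra <- setdiff(colnames(dat), schema$features$name)
  if (length(extra))
    stop("unknown column not in schema: '", extra[1], "'", call. = FALSE)
  tab <- cohort_table(dat, y, schema, allow_missing = allow_missing)
  if (!quiet)
    message("loaded cohort: ", nrow(tab$data), " rows, ", ncol(tab$data),
            " features, ", round(100 * mean(tab$mask), 2), "% cells missing")
  tab
}

#' Write a cohort table to delimited text
#'
#' Inverse of [load_cohort()]: masked cells are written as empty strings.
#'
#' @param table A [cohort_table()].
#' @param path Output path; `.tsv` writes tab-separated, else comma.
#' @param label_col Name for the label column.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, label_col = "label") {
  stopifnot(inherits(table, "cohort_table"))
  out <- table$data
  for (nm in colnames(out)) out[[nm]] <- as.character(out[[nm]])
  out[[label_col]] <- as.character(table$y)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Reproducible train/test split
#'
#' Draws `round(f * n)` training rows, stratified by the outcome when `y` is
#' supplied (the default pipeline always stratifies, so the rare diabetic
#' class cannot vanish from a 20% test set). Per-class training counts use
#' largest-remainder rounding so the total is exactly `round(f * n)`.
#'
#' @param n Number of rows.
#' @param seed Integer seed; the same `(n, seed, f)` always yields the same
#'   split.
#' @param f Training fraction, strictly between 0 and 1 (default 0.8).
#' @param y Optional outcome vector of length `n` for stratification.
#' @return An object of class `trial_split`: list with `seed`, `f`, sorted
#'   integer `train` and `test` index vectors.
#' @export
trial_split <- function(n, seed, f = 0.8, y = NULL) {
  stopifnot(f > 0, f < 1, n >= 2)
  n_train <- round(f * n)
  if (n_train >= n || n_train < 1)
    stop("n too small to leave at least one train and one test row",
         call. = FALSE)
  train <- with_seed(seed, {
    if (is.null(y)) {
      sort(sample.int(n, n_train))
    } else {
      stopifnot(length(y) == n)
      y <- as.factor(y)
      idx_by <- split(seq_len(n), y, drop = TRUE)
      quota <- vapply(idx_by, length, 1L) * f
      base <- floor(quota)
      rem <- n_train - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      picked <- unlist(Map(function(ix, k) {
        if (k >= length(ix)) ix else if (k <= 0) integer(0)
        else ix[sample.int(length(ix), k)]
      }, idx_by, base), use.names = FALSE)
      sort(picked)
    }
  })
  structure(list(seed = seed, f = f, train = train,
                 test = setdiff(seq_len(n), train)),
            class = "trial_split")
}

#' @export
print.trial_split <- function(x, ...) {
  cat("<trial_split> seed=", x$seed, ", ", length(x$train), " train / ",
      length(x$test), " test\n", sep = "")
  invisible(x)
}

#' Serialize / restore a split as JSON
#' @param split A [trial_split()].
#' @param path JSON file path.
#' @return `split_to_json` returns `path` invisibly; `split_from_json`
#'   returns a `trial_split`.
#' @export
split_to_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname split_to_json
#' @export
split_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(seed = x$seed, f = x$f, train = as.integer(x$train),
                 test = as.integer(x$test)), class = "trial_split")
}

#' Write / read a schema as YAML
#' @param schema A [feature_schema()].
#' @param path YAML file path.
#' @return `schema_to_yaml` returns `path` invisibly; `schema_from_yaml`
#'   returns a `feature_schema`.
#' @export
schema_to_yaml <- function(schema, path) {
  out <- lapply(c(D = "D", C = "C", S_lif = "S_lif", S_gen = "S_gen"),
    function(g) {
      nms <- schema_features(schema, g)
      stats::setNames(lapply(nms, function(nm) {
        if (nm %in% names(schema$levels)) as.list(schema$levels[[nm]])
        else "numeric"
      }), nms)
    })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname schema_to_yaml
#' @export
schema_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  conv <- function(g) lapply(raw[[g]], function(v) {
    if (identical(v, "numeric")) "numeric" else unlist(v)
  })
  feature_schema(D = conv("D"), C = conv("C"),
                 S_lif = conv("S_lif"), S_gen = conv("S_gen"))
}
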