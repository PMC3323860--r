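# Readers and writers for the tabular interchange formats: TSV (comma
# fallback by sniffing), header row of feature identifiers, first column =
# sample id, UTF-8, '.' decimal. Lines starting with '#' are treated as
# comments (the CLI writes its provenance there).

sniff_delim <- function(path) {
  first <- readLines(path, n = 10)
  first <- first[!startsWith(first, "#")][1]
  if (is.na(first)) stop("empty file: ", path)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Read a feature matrix from TSV/CSV
#'
#' Expects a header row of feature identifiers with the first column
#' holding sample ids. Values must be numeric and complete; duplicate
#' feature ids, ragged rows and non-numeric cells are rejected with the
#' offending location.
#'
#' @param path File path (tab- or comma-separated; sniffed).
#' @param standardize Center and scale each feature column (default TRUE;
#'   constant columns are left at 0 with a warning).
#' @return A tibble whose first column, `sample_id`, is character and whose
#'   remaining columns are numeric features.
#' @export
read_feature_matrix <- function(path, standardize = TRUE) {
  delim <- sniff_delim(path)
  # readr silently repairs duplicate names, so check the raw header first
  raw_header <- readLines(path, n = 50)
  raw_header <- raw_header[!startsWith(raw_header, "#")][1]
  header <- strsplit(raw_header, delim, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header)) {
    stop("duplicate feature id(s) in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "sample_id"
  feats <- names(df)[-1]
  for (col in feats) {
    if (!is.numeric(df[[col]])) {
      stop("non-numeric values in feature column '", col, "'")
    }
    if (anyNA(df[[col]])) {
      stop("missing values in feature column '", col, "' (rows ",
           paste(utils::head(which(is.na(df[[col]])), 5), collapse = ", "), ")")
    }
  }
  df$sample_id <- as.character(df$sample_id)
  if (standardize) {
    df <- standardize_features(df)
  }
  df
}

#' Center and scale feature columns
#'
#' Standardizes every numeric column of a data frame to mean 0 and unit
#' standard deviation. Constant columns carry no information and are set
#' to 0 with a warning.
#'
#' @param df A data frame; non-numeric columns (e.g. sample ids) pass
#'   through untouched.
#' @return The standardized tibble.
#' @export
standardize_features <- function(df) {
  df <- tibble::as_tibble(df)
  num <- vapply(df, is.numeric, logical(1))
  consts <- character(0)
  for (col in names(df)[num]) {
    s <- stats::sd(df[[col]])
    if (s == 0) {
      consts <- c(consts, col)
      df[[col]] <- rep(0, nrow(df))
    } else {
      df[[col]] <- (df[[col]] - mean(df[[col]])) / s
    }
  }
  if (length(consts) > 0) {
    warning("constant feature column(s) set to 0: ",
            paste(consts, collapse = ", "))
  }
  df
}

#' Read binary targets from TSV/CSV
#'
#' @param path File path; header row, first column = sample id.
#' @param primary Name of the primary target column.
#' @param secondaries Character vector of secondary target columns
#'   (possibly empty).
#' @return A tibble of validated 0/1 integer columns, primary first.
#' @export
read_targets <- function(path, primary, secondaries = character(0)) {
  delim <- sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  wanted <- c(primary, secondaries)
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0) {
    stop("target column(s) not found: ", paste(missing, collapse = ", "))
  }
  out <- df[wanted]
  for (col in wanted) {
    vals <- out[[col]]
    bad <- !(vals %in% c(0, 1))
    if (any(bad)) {
      stop("non-binary values in target '", col, "': ",
           paste(utils::head(unique(vals[bad]), 5), collapse = ", "))
    }
    out[[col]] <- as.integer(vals)
  }
  tibble::as_tibble(out)
}

#' Write a sample-by-feature table as TSV
#'
#' @param df Data frame; a `sample_id` column is added if absent.
#' @param path Output path.
#' @param header Optional character vector written as leading `#` comment
#'   lines (provenance).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(df, path, header = NULL) {
  if (!"sample_id" %in% names(df)) {
    df <- dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("s", seq_len(nrow(df)))), df
    )
  }
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Read a multi-study manifest
#'
#' JSON array of objects with fields `name`, `matrix_path`, `targets_path`,
#' `primary_col` and optionally `secondary_cols`; paths are resolved
#' relative to the manifest's directory.
#'
#' @param path Manifest path.
#' @param standardize Standardize each study's features on load.
#' @return A named list of studies (`features` + `targets`) suitable for
#'   [pooled_forward_rank()], [holdout_protocol()] and [lodo_protocol()].
#' @export
read_study_manifest <- function(path, standardize = TRUE) {
  entries <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  studies <- lapply(entries, function(e) {
    feats <- read_feature_matrix(resolve(e$matrix_path),
                                 standardize = standardize)
    targs <- read_targets(resolve(e$targets_path), e$primary_col,
                          unlist(e$secondary_cols) %||% character(0))
    if (nrow(feats) != nrow(targs)) {
      stop("study '", e$name, "': features and targets disagree on rows")
    }
    list(features = feats[-1], targets = targs)
  })
  names(studies) <- vapply(entries, function(e) e$name, character(1))
  studies
}
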