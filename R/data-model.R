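#' @keywords internal
"_PACKAGE"

# Closed vocabularies for the long-format table.
REGIONS <- c("cortical_gm", "white_matter", "tbv", "hippocampus", "amygdala",
             "caudate", "putamen", "pallidum", "accumbens", "thalamus", "etiv")
SEXES <- c("female", "male")

# Required columns of the canonical long table (one row per
# subject-visit-region). euler / software / etiv are optional covariates.
REQUIRED_COLS <- c("subject_id", "wave", "age", "sex", "region", "volume")
OPTIONAL_COLS <- c("euler", "software", "etiv")

#' Construct and validate a long-format volume dataset
#'
#' The canonical container for all modelling stages: one row per
#' subject-visit-region with columns \code{subject_id}, \code{wave} (integer
#' 1..12), \code{age} (decimal years), \code{sex} (\code{female}/\code{male},
#' female is the reference level throughout), \code{region} (closed
#' vocabulary of global and subcortical structures), \code{volume} (mm^3),
#' and optionally \code{euler} (mean Euler number across hemispheres, a
#' motion/quality proxy, typically negative), \code{software} (scanner
#' software version) and \code{etiv}. Missing visits are absent rows, never
#' sentinel values; mixed models tolerate the resulting unbalanced design.
#'
#' Invariants checked: positive ages and volumes, sex/region drawn from their
#' vocabularies, within a subject ages strictly increasing with wave, and at
#' most one record per (subject, wave, region). Violations raise errors that
#' name the offending rows.
#'
#' @param df a data.frame with at least the required columns.
#' @param study optional study label stored as metadata.
#' @return The validated data.frame with class \code{long_volumes} and a
#'   \code{rescale} attribute recording any per-region divisor applied
#'   (see \code{\link{rescale_volumes}}).
#' @export
long_volumes <- function(df, study = NULL) {
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$wave <- as.integer(df$wave)
  df$sex <- as.character(df$sex)
  df$region <- as.character(df$region)

  fail_rows <- function(ok, what) {
    if (!all(ok)) {
      stop(what, " at row(s) ", paste(utils::head(which(!ok), 10), collapse = ", "),
           call. = FALSE)
    }
  }
  fail_rows(is.finite(df$age) & df$age > 0, "age must be finite and > 0")
  fail_rows(is.finite(df$volume) & df$volume > 0, "volume must be finite and > 0")
  fail_rows(df$sex %in% SEXES, "sex must be one of {female, male}")
  fail_rows(df$region %in% REGIONS, "unknown region label")
  fail_rows(!is.na(df$wave) & df$wave >= 1L & df$wave <= 12L,
            "wave must be an integer in 1..12")

  key <- paste(df$subject_id, df$wave, df$region, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, wave, region) record(s) at row(s) ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  }
  # ages strictly increasing with wave within subject (per region)
  ord <- order(df$subject_id, df$region, df$wave)
  sdf <- df[ord, ]
  same_series <- c(FALSE, sdf$subject_id[-1] == sdf$subject_id[-nrow(sdf)] &
                            sdf$region[-1] == sdf$region[-nrow(sdf)])
  nondec <- same_series & c(FALSE, diff(sdf$age) <= 0)
  if (any(nondec)) {
    stop("within-subject ages must be strictly increasing with wave; ",
         "violated at original row(s) ",
         paste(utils::head(ord[which(nondec)], 10), collapse = ", "),
         call. = FALSE)
  }

  structure(as.data.frame(df, stringsAsFactors = FALSE),
            rescale = attr(df, "rescale") %||% setNames(numeric(0), character(0)),
            study = study %||% attr(df, "study"),
            class = c("long_volumes", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.long_volumes <- function(x, ...) {
  rs <- attr(x, "rescale")
  cat("<long_volumes> ", nrow(x), " observations, ",
      length(unique(x$subject_id)), " subjects, ",
      length(unique(x$region)), " region(s)\n", sep = "")
  if (length(rs)) {
    cat("  rescaled regions: ",
        paste(sprintf("%s (/%g)", names(rs), rs), collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

#' Read / write a long-format volume table
#'
#' Reads a delimited UTF-8 text file (comma or tab separated, "." decimal
#' separator, empty field = missing) into a validated
#' \code{\link{long_volumes}} dataset. Column names can be remapped via
#' \code{col_map} for files whose headers differ from the canonical names;
#' unknown extra columns are carried through untouched as opaque covariates.
#' Non-numeric entries in numeric columns are reported with their row number.
#'
#' @param path file path.
#' @param sep field delimiter; \code{","} (default) or \code{"\t"}.
#' @param col_map named character vector mapping canonical names to the
#'   file's header names, e.g. \code{c(subject_id = "SID")}.
#' @return \code{read_long_table}: a \code{long_volumes} dataset.
#' @export
read_long_table <- function(path, sep = ",", col_map = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL)
  # apply header remapping (canonical <- file name)
  for (canon in names(col_map)) {
    src <- col_map[[canon]]
    if (!src %in% names(raw)) {
      stop("mapped column '", src, "' (for '", canon, "') not in header",
           call. = FALSE)
    }
    names(raw)[names(raw) == src] <- canon
  }
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  parse_num <- function(x, col, required) {
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop("non-numeric value in column '", col, "' at row ",
           paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
    }
    if (required && anyNA(out)) {
      stop("missing value in required column '", col, "' at row ",
           paste(utils::head(which(is.na(out)), 10), collapse = ", "),
           call. = FALSE)
    }
    out
  }
  raw$wave <- parse_num(raw$wave, "wave", TRUE)
  raw$age <- parse_num(raw$age, "age", TRUE)
  raw$volume <- parse_num(raw$volume, "volume", TRUE)
  for (col in c("euler", "etiv")) {
    if (col %in% names(raw)) raw[[col]] <- parse_num(raw[[col]], col, FALSE)
  }
  long_volumes(raw)
}

#' @rdname read_long_table
#' @param data a \code{long_volumes} dataset.
#' @return \code{write_long_table}: the path, invisibly.
#' @export
write_long_table <- function(data, path, sep = ",") {
  utils::write.table(as.data.frame(data), path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Average left and right hemisphere volumes
#'
#' Subcortical structures are analysed as the arithmetic mean of their left
#' and right hemisphere volumes.
#'
#' @param left,right positive volumes in mm^3 (vectorized).
#' @return The elementwise arithmetic mean.
#' @examples
#' average_hemispheres(4000, 4200)  # 4100
#' @export
average_hemispheres <- function(left, right) {
  if (any(left <= 0) || any(right <= 0)) {
    stop("average_hemispheres: volumes must be > 0", call. = FALSE)
  }
  (left + right) / 2
}

#' Rescale volumes for selected regions
#'
#' Divides the volumes of the named regions by a constant (conventionally 100
#' for the global measures, which otherwise cause convergence trouble in
#' nonlinear mixed models because of their large numeric scale). The divisor
#' is recorded per region in the dataset's \code{rescale} attribute and all
#' parameter estimates for those regions are then on the rescaled scale.
#' Re-rescaling an already-rescaled region is refused.
#'
#' @param data a \code{long_volumes} dataset.
#' @param regions character vector of region labels to rescale.
#' @param divisor positive divisor (typically 100).
#' @return The rescaled \code{long_volumes} dataset.
#' @export
rescale_volumes <- function(data, regions, divisor = 100) {
  stopifnot(inherits(data, "long_volumes"))
  if (divisor <= 0) stop("divisor must be > 0", call. = FALSE)
  rs <- attr(data, "rescale")
  already <- intersect(regions, names(rs)[rs != 1])
  if (divisor != 1 && length(already)) {
    stop("region(s) already rescaled: ", paste(already, collapse = ", "),
         "; refusing to rescale twice", call. = FALSE)
  }
  sel <- data$region %in% regions
  data$volume[sel] <- data$volume[sel] / divisor
  if (divisor != 1) rs[regions] <- divisor
  attr(data, "rescale") <- rs
  data
}

#' Undo a recorded per-region rescaling
#'
#' @param data a rescaled \code{long_volumes} dataset.
#' @param regions regions to restore to their original scale (default: all
#'   recorded ones).
#' @return The dataset on the original mm^3 scale for those regions.
#' @export
unrescale_volumes <- function(data, regions = NULL) {
  stopifnot(inherits(data, "long_volumes"))
  rs <- attr(data, "rescale")
  regions <- regions %||% names(rs)
  for (r in intersect(regions, names(rs))) {
    sel <- data$region == r
    data$volume[sel] <- data$volume[sel] * rs[[r]]
    rs <- rs[names(rs) != r]
  }
  attr(data, "rescale") <- rs
  data
}
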