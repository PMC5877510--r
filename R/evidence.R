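#' Declared column vocabulary for line-of-evidence tables
#'
#' Returns the schema used to validate evidence tables: canonical
#' (snake_case) column names, header aliases, categorical state
#' vocabularies mirroring the screening database discretizations, units
#' for numeric physico-chemical criteria, and the missing-value markers
#' accepted on disk.
#'
#' @return A list with elements `missing_markers`, `aliases`,
#'   `categorical`, `numeric_units`, `precomputed`, `tox_cols`,
#'   `quality_cols`.
#' @export
default_loe_schema <- function() {
  list(
    missing_markers = c("-", "", "NA"),
    # arbitrary file headers -> canonical names
    aliases = c(
      "id"                 = "loe_id",
      "id_j"               = "loe_id",
      "case"               = "loe_id",
      "nanoparticle"       = "nm",
      "nanomaterial"       = "nm",
      "s_j_pchem"          = "s_pchem",
      "s_j_tox"            = "s_tox",
      "s_j"                = "s_total",
      "w_j"                = "w",
      "w_j_norm"           = "w_norm",
      "wi_j"               = "wi",
      "surface_area_m2_g"  = "surface_area",
      "particle_size_nm"   = "particle_size"
    ),
    categorical = list(
      admin_route  = c("oral", "inhalation", "injection", "intravenous"),
      study_type   = c("in vitro", "in vivo"),
      hazard_label = c("None", "Low", "Medium", "High"),
      shape        = c("sphere", "elongated", "irregular", "amorphous"),
      dissolution  = c("0-25%", "25-50%", ">50%"),
      surface_area = c("0-15", "15-51", "51-101.25", "101.25-189",
                       "189-2025", ">51"),
      surface_charge = c("from -50 to -25", "from -25 to 0", "0-25",
                         "25-50"),
      surface_coatings  = c("none", "coated"),
      surface_reactivity = c("low", "medium", "high"),
      aggregation  = c("low", "medium", "high"),
      particle_size = c("0-10", "10-50", "50-100", ">100")
    ),
    numeric_units = c(
      bet_surface_area = "m2/g", primary_particle_size = "nm",
      aspect_ratio = "ratio", zeta_potential = "mV",
      purity = "%", dissolution_pct = "%"
    ),
    precomputed = c("s_pchem", "s_tox", "s_total", "w", "w_norm", "wi"),
    tox_cols = paste0("d", 1:5),
    quality_cols = c("q_adequacy", "q_reliability", "q_power",
                     "q_significance")
  )
}

#' Construct and validate an evidence table
#'
#' An evidence table holds one row per line of evidence (LOE) — a single
#' experimental result extracted from a study — for one nanomaterial.
#' Rows may carry raw per-criterion data (physico-chemical states,
#' toxicity-class likelihoods `d1..d5`, study-quality criteria `q_*`),
#' precomputed index columns (`s_pchem`, `s_tox`, `s_total`, `w`,
#' `w_norm`, `wi`), or both.
#'
#' @param x data.frame with at least `loe_id` and `nm` columns.
#' @param nm optional nanomaterial label; defaults to the single value of
#'   the `nm` column.
#' @param schema schema list, see [default_loe_schema()].
#' @param check_precomputed if `TRUE`, verify that precomputed `w_norm`
#'   and `wi` columns are consistent with `w` and `s_total` at printed
#'   precision (tolerance 0.02, two-decimal rounding accumulation).
#' @return The validated data.frame with class `evidence_table` and an
#'   `nm` attribute.
#' @export
evidence_table <- function(x, nm = NULL, schema = default_loe_schema(),
                           check_precomputed = TRUE) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"loe_id" %in% names(x)) stop("evidence table needs a 'loe_id' column")
  if (!"nm" %in% names(x) && is.null(nm)) {
    stop("evidence table needs an 'nm' column or an explicit nm label")
  }
  if (!"nm" %in% names(x)) x$nm <- nm
  if (nrow(x) > 0) {
    if (anyDuplicated(x$loe_id)) stop("duplicated loe_id values")
    if (any(is.na(x$nm) | !nzchar(x$nm))) stop("nm labels must be non-empty")
  }
  if (is.null(nm)) nm <- if (nrow(x)) x$nm[[1L]] else NA_character_

  for (col in intersect(names(schema$categorical), names(x))) {
    states <- schema$categorical[[col]]
    bad <- !is.na(x[[col]]) & !(x[[col]] %in% states)
    if (any(bad)) {
      stop(sprintf("column '%s': undeclared state '%s' in row %d",
                   col, x[[col]][which(bad)[1L]], which(bad)[1L]))
    }
  }

  dcols <- schema$tox_cols
  if (all(dcols %in% names(x)) && nrow(x) > 0) {
    d <- as.matrix(x[, dcols])
    has_d <- rowSums(is.na(d)) < ncol(d)
    if (any(has_d)) {
      dd <- d[has_d, , drop = FALSE]
      if (anyNA(dd)) stop("toxicity likelihoods d1..d5 must be jointly present")
      if (any(dd < 0 | dd > 1)) stop("toxicity likelihoods must lie in [0,1]")
      s <- rowSums(dd)
      if (any(abs(s - 1) > 1e-9)) {
        stop(sprintf("toxicity likelihoods in row %d sum to %.4g, not 1",
                     which(has_d)[which(abs(s - 1) > 1e-9)[1L]],
                     s[which(abs(s - 1) > 1e-9)[1L]]))
      }
    }
  }

  qcols <- intersect(schema$quality_cols, names(x))
  for (col in qcols) {
    v <- x[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(sprintf("quality criterion '%s' outside [0,1]", col))
    }
  }
  if ("w" %in% names(x) && any(!is.na(x$w) & (x$w < 0 | x$w > 1))) {
    stop("study-quality weights w must lie in [0,1]")
  }

  if (check_precomputed && nrow(x) > 0 &&
      all(c("w", "w_norm", "wi", "s_total") %in% names(x)) &&
      !anyNA(x$w) && !anyNA(x$wi)) {
    wn <- x$w / sum(x$w)
    if (any(abs(wn - x$w_norm) > 0.02)) {
      stop("precomputed w_norm inconsistent with w (tolerance 0.02)")
    }
    if (any(abs(x$s_total * wn - x$wi) > 0.02)) {
      stop("precomputed wi inconsistent with s_total * w_norm (tolerance 0.02)")
    }
  }

  class(x) <- c("evidence_table", "data.frame")
  attr(x, "nm") <- nm
  x
}

canonical_order <- c(
  "loe_id", "reference", "nm",
  "shape", "dissolution", "surface_area", "surface_charge",
  "surface_coatings", "surface_reactivity", "aggregation",
  "particle_size", "bet_surface_area", "primary_particle_size",
  "aspect_ratio", "zeta_potential", "purity",
  "admin_route", "study_type", "hazard_label",
  paste0("d", 1:5),
  "q_adequacy", "q_reliability", "q_power", "q_significance",
  "w_override",
  "s_pchem", "s_tox", "s_total", "w", "w_norm", "wi"
)

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read an evidence table from delimited text
#'
#' Reads a CSV/TSV file with a header, normalizes headers to canonical
#' snake_case names via the schema aliases, converts the declared
#' missing-value markers to `NA`, coerces numeric columns, and validates
#' the result.
#'
#' @param path file path.
#' @param schema see [default_loe_schema()].
#' @param delim field delimiter; `NULL` auto-detects comma vs tab from
#'   the header line.
#' @inheritParams evidence_table
#' @return An [evidence_table()].
#' @export
read_evidence_table <- function(path, schema = default_loe_schema(),
                                delim = NULL, nm = NULL,
                                check_precomputed = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(delim)) delim <- sniff_delim(path)
  x <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE, comment.char = "",
                         strip.white = TRUE)
  nm_map <- schema$aliases
  hdr <- tolower(gsub("[^A-Za-z0-9]+", "_", trimws(names(x))))
  hdr <- sub("^_+|_+$", "", hdr)
  hit <- hdr %in% names(nm_map)
  hdr[hit] <- unname(nm_map[hdr[hit]])
  names(x) <- hdr

  for (col in names(x)) {
    x[[col]][x[[col]] %in% schema$missing_markers] <- NA_character_
  }
  numeric_cols <- c(schema$precomputed, schema$tox_cols, schema$quality_cols,
                    names(schema$numeric_units), "w_override")
  for (col in intersect(numeric_cols, names(x))) {
    raw <- x[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(val)
    if (any(bad)) {
      stop(sprintf("malformed value '%s' in row %d, column '%s'",
                   raw[which(bad)[1L]], which(bad)[1L], col))
    }
    x[[col]] <- val
  }
  evidence_table(x, nm = nm, schema = schema,
                 check_precomputed = check_precomputed)
}

#' Write an evidence table to delimited text
#'
#' Columns are emitted in canonical order (identity, raw criteria, then
#' the precomputed index columns in report order). Missing values are
#' written as `"-"`. Numeric values are written at full precision so
#' that `read_evidence_table(write_evidence_table(t))` round-trips.
#'
#' @param table an [evidence_table()].
#' @param path output path; delimiter chosen from the extension
#'   (`.tsv` gives tab) unless `delim` is supplied.
#' @param delim optional field delimiter.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(table, path, delim = NULL) {
  stopifnot(inherits(table, "evidence_table"))
  if (is.null(delim)) delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  ord <- c(intersect(canonical_order, names(table)),
           setdiff(names(table), canonical_order))
  out <- as.data.frame(table)[, ord, drop = FALSE]
  for (col in names(out)) {
    v <- out[[col]]
    out[[col]] <- if (is.numeric(v)) {
      ifelse(is.na(v), "-", sprintf("%.17g", v))
    } else {
      ifelse(is.na(v), "-", as.character(v))
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Bundled nano-TiO2 weight-of-evidence table
#'
#' The published 22-line-of-evidence table for nano-TiO2 at printed
#' (two-decimal) precision: per-LOE physico-chemical index `s_pchem`,
#' toxicity index `s_tox`, aggregated index `s_total`, study-quality
#' weight `w`, normalized weight `w_norm`, and weighted index `wi`.
#' The `wi` column sums to the published hazard score V = 44.24 up to
#' two-decimal rounding accumulation.
#'
#' @return An [evidence_table()] with 22 rows.
#' @export
tio2_fixture <- function() {
  path <- system.file("extdata", "tio2_woe_table1.csv",
                      package = "nanoscreen", mustWork = TRUE)
  read_evidence_table(path)
}

#' @export
print.evidence_table <- function(x, ...) {
  cat(sprintf("Evidence table: %s (%d LOE)\n", attr(x, "nm"), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}
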