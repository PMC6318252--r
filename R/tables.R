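## CSV interchange tables: per-residue annotations, protection-factor
## tables, peptide definitions and microstate ensembles. All tables are
## comma-separated UTF-8 with a header row and '.' decimal; numeric columns
## are written with 17 significant digits so that write/read round-trips are
## bit exact.

table_schemas <- list(
  annotation = list(required = c("chain", "resno"),
                    numeric = c("resno", "logPF_measured", "burial"),
                    unique_key = c("chain", "resno")),
  pf = list(required = c("chain", "resno", "logPF"),
            numeric = c("resno", "logPF", "PF", "dG_ex", "k_int"),
            unique_key = c("chain", "resno")),
  peptide = list(required = c("peptide", "chain", "start", "end", "sequence"),
                 numeric = c("start", "end"),
                 unique_key = "peptide"),
  microstate = list(required = c("state", "dG_s"),
                    numeric = "dG_s",
                    unique_key = "state")
)

#' Validate an interchange table against its schema
#'
#' Checks required columns, key uniqueness and closed category sets for
#' the table kinds described in [read_table()]. Called automatically by
#' [read_table()] and [write_table()].
#'
#' @param df Data frame to validate.
#' @param kind Table kind (see [read_table()]).
#' @return `df`, invisibly; errors describe the violated constraint.
#' @export
validate_table <- function(df, kind) {
  schema <- table_schemas[[kind]]
  if (is.null(schema)) stop("unknown table kind: ", kind)
  miss <- setdiff(schema$required, names(df))
  if (length(miss))
    stop("schema error: ", kind, " table is missing required column(s): ",
         paste(miss, collapse = ", "))
  key <- do.call(paste, c(df[schema$unique_key], sep = "|"))
  if (anyDuplicated(key))
    stop("uniqueness violation in ", kind, " table: duplicated key(s) ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (kind == "annotation") {
    if (!is.null(df$motion)) {
      bad <- setdiff(stats::na.omit(unique(df$motion)), MOTION_CATEGORIES)
      if (length(bad))
        stop("invalid motion category value(s): ",
             paste(bad, collapse = ", "), "; valid categories are: ",
             paste(MOTION_CATEGORIES, collapse = ", "))
    }
    if (!is.null(df$hbond)) {
      bad <- setdiff(stats::na.omit(unique(df$hbond)), HBOND_CATEGORIES)
      if (length(bad))
        stop("invalid hbond category value(s): ",
             paste(bad, collapse = ", "), "; valid categories are: ",
             paste(HBOND_CATEGORIES, collapse = ", "))
    }
    if (!is.null(df$logPF_measured) &&
        any(!is.na(df$logPF_measured) & !is.finite(df$logPF_measured)))
      stop("logPF_measured must be finite where present")
  }
  if (kind == "peptide") {
    if (any(df$start > df$end)) stop("peptide start must be <= end")
    if (any(nchar(df$sequence) != df$end - df$start + 1))
      stop("peptide sequence length inconsistent with residue span")
  }
  invisible(df)
}

#' Read an interchange table from CSV
#'
#' @param path CSV file path with a header row.
#' @param kind Table kind: `"annotation"` (per-residue measured logPFs and
#'   motion/burial/H-bond annotations), `"pf"` (per-residue protection
#'   factors), `"peptide"` (peptide definitions) or `"microstate"`
#'   (microstate free energies and per-residue folded/exposed flags).
#' @return A data frame validated against the table's schema; unknown
#'   columns are preserved.
#' @export
read_table <- function(path, kind = c("annotation", "pf", "peptide",
                                      "microstate")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_table(df, kind)
  df
}

#' Write an interchange table to CSV
#'
#' Writes comma-separated UTF-8 with '.' decimal; doubles are rendered with
#' 17 significant digits so that `read_table(write_table(x))` reproduces `x`
#' exactly.
#'
#' @param df Data frame to write.
#' @param path Output CSV path.
#' @param kind Table kind (see [read_table()]); validated before writing.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, kind = c("annotation", "pf", "peptide",
                                           "microstate")) {
  kind <- match.arg(kind)
  validate_table(df, kind)
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                          sprintf("%.17g", out[[nm]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Parse a microstate table into an ensemble
#'
#' A microstate table has one row per state with columns `state`, `dG_s`
#' (kcal/mol), per-residue flags `folded_<residue>` and `exposed_<residue>`
#' (0/1), and optionally `pr_i_<residue>` giving the ensemble probability
#' that the residue is solvent accessible (used by the COREX protection
#' factor; defaults to 0 when absent).
#'
#' @param df Data frame as returned by `read_table(path, "microstate")`.
#' @return A list with `dG` (numeric vector), `folded` and `exposed`
#'   (logical state-by-residue matrices with residue names as columns) and
#'   `pr_i` (named numeric vector).
#' @export
as_microstate_ensemble <- function(df) {
  validate_table(df, "microstate")
  fcols <- grep("^folded_", names(df), value = TRUE)
  ecols <- grep("^exposed_", names(df), value = TRUE)
  res_f <- sub("^folded_", "", fcols)
  res_e <- sub("^exposed_", "", ecols)
  if (!setequal(res_f, res_e))
    stop("folded_/exposed_ columns must cover the same residues")
  res <- res_f
  folded <- as.matrix(df[fcols]) != 0
  exposed <- as.matrix(df[ecols][match(res, res_e)]) != 0
  colnames(folded) <- res
  colnames(exposed) <- res
  pcols <- grep("^pr_i_", names(df), value = TRUE)
  pr_i <- stats::setNames(rep(0, length(res)), res)
  if (length(pcols)) {
    for (pc in pcols) pr_i[sub("^pr_i_", "", pc)] <- df[[pc]][1]
  }
  list(dG = df$dG_s, folded = folded, exposed = exposed, pr_i = pr_i)
}
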