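# Reading, validation and writing of connectivity matrices, subject metadata
# and statistical result tables.

#' Construct a validated connectivity matrix
#'
#' A connectivity matrix holds non-negative tract counts between pairs of
#' brain regions (ROIs). It must be square, symmetric, zero on the diagonal,
#' and have at least two nodes.
#'
#' @param weights Numeric square matrix of tract counts.
#' @param nodes Character vector of ROI labels; defaults to existing dimnames
#'   or `"ROI_001"...` when absent.
#' @param tolerance Relative asymmetry tolerance: entries with
#'   `|w_ij - w_ji| <= tolerance * max(w)` are symmetrized by their arithmetic
#'   mean (with a message); larger asymmetries are an error.
#' @return A `connectivity_matrix`: a numeric matrix with node labels as
#'   dimnames and class attribute.
#' @export
connectivity_matrix <- function(weights, nodes = NULL, tolerance = 1e-6) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectivity matrix must be square, got ", nrow(weights), " x ",
         ncol(weights), call. = FALSE)
  }
  n <- nrow(weights)
  if (n < 2) stop("connectivity matrix needs at least 2 nodes", call. = FALSE)
  if (!is.numeric(weights) || anyNA(weights)) {
    bad <- which(is.na(suppressWarnings(weights * 1)), arr.ind = TRUE)
    stop("non-numeric or missing entry at row ", bad[1, 1], ", column ",
         bad[1, 2], call. = FALSE)
  }
  neg <- which(weights < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative entry at row ", neg[1, 1], ", column ", neg[1, 2],
         call. = FALSE)
  }
  asym <- abs(weights - t(weights))
  wmax <- max(weights)
  if (max(asym) > 0) {
    if (wmax > 0 && max(asym) > tolerance * wmax) {
      bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
      stop("asymmetry beyond tolerance at row ", bad[1], ", column ", bad[2],
           " (|w_ij - w_ji| = ", format(max(asym)), ")", call. = FALSE)
    }
    cp_msg("symmetrizing matrix by arithmetic mean (max asymmetry ",
           format(max(asym)), ")")
    weights <- (weights + t(weights)) / 2
  }
  if (any(diag(weights) != 0)) {
    cp_msg("zeroing nonzero diagonal (self-connections are ignored)")
    diag(weights) <- 0
  }
  if (is.null(nodes)) {
    nodes <- rownames(weights)
    if (is.null(nodes)) nodes <- sprintf("ROI_%03d", seq_len(n))
  }
  if (length(nodes) != n) stop("length(nodes) != matrix dimension", call. = FALSE)
  nodes <- as.character(unname(nodes))
  dimnames(weights) <- list(nodes, nodes)
  structure(weights, class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x), " nodes, ",
      sum(x[upper.tri(x)] > 0), " edges, max count ", format(max(x)), "\n",
      sep = "")
  invisible(x)
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read a connectivity matrix from a delimited text file
#'
#' Accepts CSV/TSV square numeric tables, with or without a header row and/or
#' a first column of ROI labels. Validation (squareness, non-negativity,
#' symmetry within tolerance, zero diagonal) follows
#' [connectivity_matrix()].
#'
#' @param path Path to the file.
#' @param tolerance Relative asymmetry tolerance (see [connectivity_matrix()]).
#' @return A `connectivity_matrix`.
#' @export
read_matrix <- function(path, tolerance = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  raw <- read.table(path, sep = sep, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", strip.white = TRUE)
  raw <- as.matrix(raw)
  is_num <- function(v) !anyNA(suppressWarnings(as.numeric(v)))
  nodes <- NULL
  # header row of labels?
  if (!is_num(raw[1, , drop = TRUE])) {
    hdr <- raw[1, , drop = TRUE]
    raw <- raw[-1, , drop = FALSE]
    nodes <- hdr
  }
  # label column?
  if (ncol(raw) >= 1 && !is_num(raw[, 1, drop = TRUE])) {
    lab <- raw[, 1, drop = TRUE]
    raw <- raw[, -1, drop = FALSE]
    nodes <- lab
    # header may have carried a corner cell
  }
  if (!is.null(nodes) && length(nodes) == ncol(raw) + 1) nodes <- nodes[-1]
  if (!is_num(c(raw))) stop("non-numeric entry in matrix file ", path,
                            call. = FALSE)
  w <- matrix(as.numeric(raw), nrow = nrow(raw))
  if (nrow(w) != ncol(w)) {
    stop("matrix file is not square: ", nrow(w), " x ", ncol(w), " in ", path,
         call. = FALSE)
  }
  connectivity_matrix(w, nodes = nodes, tolerance = tolerance)
}

#' Write a connectivity matrix to a delimited text file
#'
#' @param conn A `connectivity_matrix`.
#' @param path Output path; `.tsv` extension writes tab-separated, anything
#'   else comma-separated. Node labels are written as a header row.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(conn, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- as.data.frame(unclass(conn))
  names(df) <- rownames(conn)
  write.table(df, path, sep = sep, row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

default_group_aliases <- function() {
  c("control" = "control", "controls" = "control", "unexposed" = "control",
    "hc" = "control",
    "exposed_noptsd" = "exposed_noptsd", "ptsd-" = "exposed_noptsd",
    "wtc_ptsd-" = "exposed_noptsd", "exposed" = "exposed_noptsd",
    "ptsd" = "ptsd", "ptsd+" = "ptsd", "wtc_ptsd+" = "ptsd")
}

required_metadata_cols <- function() {
  c("subject_id", "group", "mdd", "age", "sex", "education", "body_mass",
    "pcl_total", "re_experiencing", "avoidance", "hyperarousal",
    "negative_affect", "overall")
}

#' Read a subject metadata table
#'
#' Reads a delimited table of one row per subject: identifiers, clinical
#' group, MDD comorbidity flag, demographic covariates and PTSD symptom
#' domain scores. The group column is parsed against the fixed ordering
#' control < exposed_noptsd < ptsd, optionally through an alias map.
#'
#' @param path Path to a CSV/TSV file with header.
#' @param aliases Named character vector mapping raw group labels (lowercased)
#'   to canonical levels; defaults cover common spellings such as `"PTSD+"`.
#' @return A data.frame of typed subject records with `group` as an ordered
#'   factor.
#' @export
read_metadata <- function(path, aliases = default_group_aliases()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   strip.white = TRUE)
  missing_cols <- setdiff(required_metadata_cols(), names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         df$subject_id[duplicated(df$subject_id)][1], call. = FALSE)
  }
  raw_group <- tolower(trimws(as.character(df$group)))
  mapped <- unname(aliases[raw_group])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    stop("unknown group label: ", unique(df$group[unknown])[1], call. = FALSE)
  }
  df$group <- factor(mapped, levels = the_group_levels, ordered = TRUE)
  df$mdd <- as.logical(df$mdd)
  num_cols <- c("age", "body_mass", "pcl_total", "re_experiencing",
                "avoidance", "hyperarousal", "negative_affect", "overall")
  if ("cortical_complexity" %in% names(df)) {
    num_cols <- c(num_cols, "cortical_complexity")
  }
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & df[[col]] != "" & is.na(v)
    if (any(bad)) {
      stop("unparseable numeric in column ", col, ", row ", which(bad)[1],
           call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Write a subject metadata table
#'
#' @param records Data.frame of subject records (as from [read_metadata()]).
#' @param path Output path (`.tsv` for tab-separated).
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- records
  out$group <- as.character(out$group)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a statistical result row
#'
#' Uniform container for every test in the battery: a one-row data.frame
#' carrying the method label, contrast, point estimate, standardized effect
#' size (Cohen's d, rho, or standardized beta), test statistic, degrees of
#' freedom, p-value, optional adjusted p-value and the n used.
#'
#' @param method,contrast Labels.
#' @param estimate,effect_size,statistic,df,p,p_adjusted Numerics (NA allowed
#'   where undefined).
#' @param n Integer number of observations used.
#' @return A one-row data.frame of class `stat_result`.
#' @export
stat_result <- function(method, contrast = NA_character_, estimate = NA_real_,
                        effect_size = NA_real_, statistic = NA_real_,
                        df = NA_real_, p = NA_real_, p_adjusted = NA_real_,
                        n = NA_integer_) {
  if (!is.na(p) && (p < 0 || p > 1)) stop("p outside [0, 1]", call. = FALSE)
  out <- data.frame(method = method, contrast = contrast, estimate = estimate,
                    effect_size = effect_size, statistic = statistic, df = df,
                    p = p, p_adjusted = p_adjusted, n = as.integer(n),
                    stringsAsFactors = FALSE)
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Bind statistical results into one table
#'
#' @param results A list of `stat_result` rows (or data.frames of them).
#' @return A data.frame with one row per result.
#' @export
bind_results <- function(results) {
  if (length(results) == 0) stop("results must be non-empty", call. = FALSE)
  out <- do.call(rbind, lapply(results, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Write a table of statistical results
#'
#' Values are written with 15 significant digits so a write/read round trip
#' preserves them to at least 12 significant digits.
#'
#' @param results List of `stat_result` rows or a bound results data.frame.
#' @param path Output path (`.tsv` for tab-separated).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.data.frame(results)) {
    if (nrow(results) == 0) stop("results must be non-empty", call. = FALSE)
    tab <- results
  } else {
    tab <- bind_results(results)
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) {
    out <- vapply(v, function(x) formatC(x, digits = 15, format = "g"), "")
    trimws(out)
  })
  write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the file.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  sep <- sniff_sep(path)
  read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
             strip.white = TRUE)
}
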