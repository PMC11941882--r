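#' The nine metal ions quantified in the aged liquor
#'
#' Order is fixed and used throughout the package: feature matrices, rankers
#' and planted-structure bookkeeping all index ions by these names.
#' @export
ION_NAMES <- c("Ca", "Na", "Mg", "Al", "K", "Fe", "Mn", "Cu", "Zn")

#' Months at which flavor substances are observed (study design)
#' @export
FLAVOR_MONTHS <- c(0L, 4L, 8L, 12L, 16L, 20L)

#' Months at which metal ions are observed (slow early drift, so sparser)
#' @export
ION_MONTHS <- c(0L, 12L, 16L, 20L)

#' Construct a validated jar-parameter table
#'
#' One row per pottery jar: trace-metal content of the clay (Cu, Fe, Zn, mg/L)
#' and the maximum/minimum pore size (\eqn{\mu m}) of the fired wall.
#'
#' @param df data.frame with columns `jar_id, cu, fe, zn, p_max, p_min`.
#' @return data.frame of class `jar_table`.
#' @export
jar_table <- function(df) {
  need <- c("jar_id", "cu", "fe", "zn", "p_max", "p_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    jf_stop("jf_schema_error", "jar table missing column(s): %s",
            paste(miss, collapse = ", "))
  df <- df[need]
  df$jar_id <- as.integer(df$jar_id)
  for (cn in need[-1]) df[[cn]] <- as.numeric(df[[cn]])
  if (anyNA(df))
    jf_stop("jf_parse_error", "jar table contains non-numeric or missing cells")
  if (anyDuplicated(df$jar_id))
    jf_stop("jf_validation_error", "duplicate jar_id in jar table")
  if (any(df[-1] < 0))
    jf_stop("jf_validation_error", "jar parameters must be non-negative")
  bad <- which(df$p_max < df$p_min)
  if (length(bad))
    jf_stop("jf_validation_error",
            "p_max < p_min for jar_id %s", paste(df$jar_id[bad], collapse = ", "))
  class(df) <- c("jar_table", "data.frame")
  df
}

#' Read a jar-parameter CSV
#'
#' Expected header: `jar_id, cu, fe, zn, p_max, p_min`. Metals in mg/L,
#' pore sizes in micrometers.
#'
#' @param path CSV file path.
#' @return `jar_table` (possibly zero rows).
#' @export
read_jar_table <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("jar_id", "cu", "fe", "zn", "p_max", "p_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    jf_stop("jf_schema_error", "jar table %s missing column(s): %s",
            path, paste(miss, collapse = ", "))
  for (cn in need) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad))
      jf_stop("jf_parse_error", "non-numeric cell in %s, row %d column %s",
              path, bad[1], cn)
    df[[cn]] <- v
  }
  jar_table(df)
}

#' Write a jar-parameter table to CSV
#' @param jars `jar_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jar_table <- function(jars, path) {
  utils::write.csv(as.data.frame(jars), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a validated ion table
#'
#' Wide layout: one row per (jar, replicate, month) sample, one column per
#' ion in [ION_NAMES] (mg/L). Zero is a legal concentration (Zn genuinely
#' drops to 0 in some jars); negative values are not.
#'
#' @param df data.frame with `jar_id, replicate, month` plus the 9 ion columns.
#' @return data.frame of class `ion_table`.
#' @export
ion_table <- function(df) {
  need <- c("jar_id", "replicate", "month", ION_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    jf_stop("jf_schema_error", "ion table missing column(s): %s",
            paste(miss, collapse = ", "))
  df <- df[need]
  df$jar_id <- as.integer(df$jar_id)
  df$replicate <- as.integer(df$replicate)
  df$month <- as.integer(df$month)
  if (nrow(df) && !all(df$month %in% ION_MONTHS))
    jf_stop("jf_validation_error", "ion months must lie in {%s}",
            paste(ION_MONTHS, collapse = ","))
  if (nrow(df) && any(as.matrix(df[ION_NAMES]) < 0, na.rm = TRUE))
    jf_stop("jf_validation_error", "ion concentrations must be non-negative")
  if (anyNA(df))
    jf_stop("jf_validation_error", "ion table contains missing values")
  key <- paste(df$jar_id, df$replicate, df$month)
  if (anyDuplicated(key))
    jf_stop("jf_validation_error", "duplicate (jar, replicate, month) ion sample")
  class(df) <- c("ion_table", "data.frame")
  df
}

#' Read an ion CSV in long layout
#'
#' Columns: `jar_id, replicate, month, ion, mg_per_l`. Every
#' (jar, replicate, month) key must carry all 9 ions of [ION_NAMES].
#'
#' @param path CSV file path.
#' @return `ion_table` (wide, one row per sample).
#' @export
read_ion_table <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("jar_id", "replicate", "month", "ion", "mg_per_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    jf_stop("jf_schema_error", "ion table %s missing column(s): %s",
            path, paste(miss, collapse = ", "))
  unknown <- setdiff(unique(df$ion), ION_NAMES)
  if (length(unknown))
    jf_stop("jf_validation_error",
            "unknown ion name(s) %s; legal names are %s",
            paste(unknown, collapse = ", "), paste(ION_NAMES, collapse = ", "))
  df$mg_per_l <- suppressWarnings(as.numeric(df$mg_per_l))
  if (anyNA(df$mg_per_l))
    jf_stop("jf_parse_error", "non-numeric concentration in %s", path)
  key <- interaction(df$jar_id, df$replicate, df$month, drop = TRUE)
  wide <- lapply(split(df, key), function(g) {
    if (!setequal(g$ion, ION_NAMES) || nrow(g) != 9L)
      jf_stop("jf_validation_error",
              "sample (jar %s, rep %s, month %s) has %d ions; all 9 required",
              g$jar_id[1], g$replicate[1], g$month[1], nrow(g))
    out <- data.frame(jar_id = g$jar_id[1], replicate = g$replicate[1],
                      month = g$month[1])
    out[g$ion] <- g$mg_per_l
    out[c("jar_id", "replicate", "month", ION_NAMES)]
  })
  wide <- do.call(rbind, c(wide, list(make.row.names = FALSE)))
  if (is.null(wide))
    wide <- stats::setNames(
      data.frame(matrix(numeric(0), 0, 12)),
      c("jar_id", "replicate", "month", ION_NAMES))
  wide <- wide[order(wide$jar_id, wide$replicate, wide$month), ]
  rownames(wide) <- NULL
  ion_table(wide)
}

#' Write an ion table as long CSV
#' @param ions `ion_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ion_table <- function(ions, path) {
  long <- do.call(rbind, lapply(ION_NAMES, function(nm) {
    data.frame(jar_id = ions$jar_id, replicate = ions$replicate,
               month = ions$month, ion = nm, mg_per_l = ions[[nm]])
  }))
  long <- long[order(long$jar_id, long$replicate, long$month, long$ion), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a validated flavor table
#'
#' Long layout: one row per (substance, jar, replicate, month) observation,
#' concentration in mg/L. The set of distinct substances is the set of
#' flavor records; `chem_class` is optional annotation.
#'
#' @param df data.frame with `substance, jar_id, replicate, month, mg_per_l`
#'   and optionally `chem_class`.
#' @return data.frame of class `flavor_table`.
#' @export
flavor_table <- function(df) {
  need <- c("substance", "jar_id", "replicate", "month", "mg_per_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    jf_stop("jf_schema_error", "flavor table missing column(s): %s",
            paste(miss, collapse = ", "))
  if (!"chem_class" %in% names(df)) df$chem_class <- NA_character_
  df <- df[c(need, "chem_class")]
  df$substance <- normalize_substance(df$substance)
  df$jar_id <- as.integer(df$jar_id)
  df$replicate <- as.integer(df$replicate)
  df$month <- as.integer(df$month)
  df$mg_per_l <- as.numeric(df$mg_per_l)
  if (anyNA(df$mg_per_l))
    jf_stop("jf_parse_error", "flavor table contains non-numeric concentrations")
  if (nrow(df) && any(df$mg_per_l < 0))
    jf_stop("jf_validation_error", "flavor concentrations must be non-negative")
  key <- paste(df$substance, df$jar_id, df$replicate, df$month)
  if (anyDuplicated(key))
    jf_stop("jf_validation_error", "duplicate (substance, jar, replicate, month) cell")
  class(df) <- c("flavor_table", "data.frame")
  df
}

# case-preserving label with whitespace collapsed; matching elsewhere is
# case-insensitive on this normalized form
normalize_substance <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x
}

#' Substance names in a flavor table
#' @param flavors `flavor_table`.
#' @return character vector of distinct substances, input order.
#' @export
flavor_substances <- function(flavors) unique(flavors$substance)

#' Read a flavor-substance CSV
#'
#' Two layouts are supported through `layout`:
#' \describe{
#'   \item{`"long"`}{columns `substance, jar_id, replicate, month, mg_per_l`
#'     (`replicate` optional, defaulting to 1).}
#'   \item{`"wide"`}{one row per substance: first column `substance`, then an
#'     optional `initial` column (month 0, shared across jars because the base
#'     liquor is identical) and columns named `m<month>_n<jar>` or
#'     `m<month>_n<jar>_r<replicate>`. Replicate-collapsed columns are stored
#'     as replicate 1.}
#' }
#'
#' @param path CSV file path.
#' @param layout `"long"` or `"wide"`.
#' @return `flavor_table`.
#' @export
read_flavor_table <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, check.names = FALSE)
  if (layout == "long") {
    if (!"replicate" %in% names(df)) df$replicate <- 1L
    return(flavor_table(df))
  }
  if (names(df)[1] != "substance")
    jf_stop("jf_schema_error", "wide flavor table must start with a 'substance' column")
  subs <- normalize_substance(df[[1]])
  if (anyDuplicated(tolower(subs)))
    jf_stop("jf_validation_error", "duplicate substance name in %s", path)
  cols <- names(df)[-1]
  m <- regmatches(cols, regexec("^m([0-9]+)_n([0-9]+)(?:_r([0-9]+))?$", cols))
  jar_set <- sort(unique(as.integer(
    vapply(m[lengths(m) > 0 & cols != "initial"], function(z) z[3], "")
  )))
  rows <- list()
  for (j in seq_along(cols)) {
    cn <- cols[j]
    vals <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(vals) & !is.na(df[[j + 1]]))
    if (length(bad))
      jf_stop("jf_parse_error", "non-numeric cell in %s, row %d column %s",
              path, bad[1], cn)
    if (cn == "initial") {
      # month 0 is the shared base liquor: replicate across every jar present
      for (jar in jar_set)
        rows[[length(rows) + 1]] <- data.frame(
          substance = subs, jar_id = jar, replicate = 1L, month = 0L,
          mg_per_l = vals)
    } else {
      z <- m[[j]]
      if (length(z) == 0)
        jf_stop("jf_schema_error",
                "unrecognized flavor column '%s' (expected 'initial' or 'm<month>_n<jar>[_r<rep>]')", cn)
      rep_i <- if (is.na(z[4]) || z[4] == "") 1L else as.integer(z[4])
      rows[[length(rows) + 1]] <- data.frame(
        substance = subs, jar_id = as.integer(z[3]), replicate = rep_i,
        month = as.integer(z[2]), mg_per_l = vals)
    }
  }
  flavor_table(do.call(rbind, rows))
}

#' Write a flavor table as long CSV
#' @param flavors `flavor_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flavor_table <- function(flavors, path) {
  utils::write.csv(as.data.frame(flavors)[
    c("substance", "jar_id", "replicate", "month", "mg_per_l")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the aligned study dataset
#'
#' Cross-checks that every ion and flavor observation references a known jar
#' and infers the design grid as the union of observed keys.
#'
#' @param jars `jar_table`.
#' @param ions `ion_table`.
#' @param flavors `flavor_table`.
#' @return list of class `study_dataset` with elements `jars`, `ions`,
#'   `flavors`, `design` (data.frame jar_id/replicate/month).
#' @export
assemble_dataset <- function(jars, ions, flavors) {
  bad_ion <- setdiff(unique(ions$jar_id), jars$jar_id)
  if (length(bad_ion))
    jf_stop("jf_linkage_error", "ion records reference unknown jar_id: %s",
            paste(bad_ion, collapse = ", "))
  bad_fl <- setdiff(unique(flavors$jar_id), jars$jar_id)
  if (length(bad_fl))
    jf_stop("jf_linkage_error", "flavor records reference unknown jar_id: %s",
            paste(bad_fl, collapse = ", "))
  design <- unique(rbind(
    ions[c("jar_id", "replicate", "month")],
    flavors[c("jar_id", "replicate", "month")]))
  design <- design[order(design$jar_id, design$replicate, design$month), ]
  rownames(design) <- NULL
  structure(list(jars = jars, ions = ions, flavors = flavors,
                 design = as.data.frame(design)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:", nrow(x$jars), "jars,",
      nrow(x$ions), "ion samples,",
      length(flavor_substances(x$flavors)), "flavor substances,",
      nrow(x$design), "design keys\n")
  invisible(x)
}

#' Aligned ion/flavor samples for one substance
#'
#' Joins ion samples with a substance's concentrations on
#' (jar, replicate, month), keeping only keys with ion data (by design,
#' months 12/16/20; month 0 is excluded because the shared base liquor
#' carries no between-jar signal).
#'
#' @param dataset `study_dataset`.
#' @param substance substance name (case-insensitive).
#' @param drop_month0 drop month-0 keys (default TRUE).
#' @return list with `X` (samples x 9 ion matrix), `y` (concentrations),
#'   `jar` (jar_id per sample).
#' @export
aligned_samples <- function(dataset, substance, drop_month0 = TRUE) {
  fl <- dataset$flavors
  sel <- tolower(fl$substance) == tolower(normalize_substance(substance))
  if (!any(sel))
    jf_stop("jf_validation_error", "unknown substance '%s'", substance)
  fl <- fl[sel, ]
  ions <- dataset$ions
  if (drop_month0) ions <- ions[ions$month != 0L, ]
  key_i <- paste(ions$jar_id, ions$replicate, ions$month)
  key_f <- paste(fl$jar_id, fl$replicate, fl$month)
  idx <- match(key_i, key_f)
  keep <- !is.na(idx)
  X <- as.matrix(ions[keep, ION_NAMES])
  rownames(X) <- NULL
  list(X = X, y = fl$mg_per_l[idx[keep]], jar = ions$jar_id[keep],
       month = ions$month[keep])
}
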