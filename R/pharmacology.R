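#' Load a pore-block drug library
#'
#' Reads a CSV drug library in the packaged dialect: one row per compound
#' with columns `name`, `<current>_ic50` and `<current>_n` for each of
#' INa, ICaL, Ito, IKr, IKs, IK1, INaCa, INaK (IC50 in uM, the string
#' `"inf"` for no measured block), `eftpc` (uM) and `true_class`
#' (`low`/`borderline`/`high`).
#'
#' @param path CSV path; default the packaged ten-compound library
#'   (IC50/Hill pore-block parameters and effective free therapeutic plasma
#'   concentrations).
#' @return `data.frame` of class `drug_library`; `ic50` columns numeric with
#'   `Inf` for no block.
#' @export
drug_library <- function(path = system.file("extdata", "drug_library.csv",
                                            package = "arscore")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", paste0(rep(DRUG_CURRENTS, each = 2),
                           c("_ic50", "_n")), "eftpc", "true_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("drug library missing column(s): ", paste(miss, collapse = ", "))
  for (cur in DRUG_CURRENTS) {
    col <- paste0(cur, "_ic50")
    df[[col]] <- ifelse(tolower(trimws(as.character(df[[col]]))) %in%
                          c("inf", "infinity"),
                        Inf, suppressWarnings(as.numeric(df[[col]])))
    if (any(is.na(df[[col]]) | df[[col]] <= 0))
      stop("invalid IC50 in column ", col)
    ncol_ <- paste0(cur, "_n")
    df[[ncol_]] <- as.numeric(df[[ncol_]])
    if (any(is.na(df[[ncol_]]) | df[[ncol_]] <= 0))
      stop("invalid Hill coefficient in column ", ncol_)
  }
  if (any(df$eftpc <= 0)) stop("eftpc must be positive")
  if (!all(df$true_class %in% c("low", "borderline", "high")))
    stop("true_class must be low/borderline/high")
  class(df) <- c("drug_library", "data.frame")
  df
}

#' Write a drug library CSV
#'
#' Serializes in the same dialect read by [drug_library()]; infinite IC50s
#' round-trip as the string `"inf"`.
#'
#' @param lib A `drug_library` data frame.
#' @param path Output path.
#' @export
write_drug_library <- function(lib, path) {
  out <- as.data.frame(lib)
  for (cur in DRUG_CURRENTS) {
    col <- paste0(cur, "_ic50")
    out[[col]] <- ifelse(is.infinite(out[[col]]), "inf",
                         format(out[[col]], trim = TRUE, scientific = FALSE))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remaining-conductance factor of the pore-block model
#'
#' `Bk = 1 / (1 + (C / IC50)^n)`: the fraction of maximal conductance
#' remaining at concentration `C`. 1 at `C = 0`; 0.5 at `C = IC50` for any
#' Hill coefficient; 1 for `IC50 = Inf` (no measured block); monotone
#' non-increasing in `C`.
#'
#' @param conc Concentration (uM), >= 0 (vectorized).
#' @param ic50 Half-maximal inhibitory concentration (uM) or `Inf`.
#' @param hill_n Hill coefficient, > 0.
#' @return Factor in (0, 1].
#' @export
block_factor <- function(conc, ic50, hill_n) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  if (any(ic50 <= 0)) stop("IC50 must be positive (or Inf)")
  if (any(hill_n <= 0)) stop("Hill coefficient must be positive")
  ifelse(is.infinite(ic50), 1, 1 / (1 + (conc / ic50)^hill_n))
}

as_drug_record <- function(drug, lib = NULL) {
  if (is.character(drug)) {
    lib <- lib %||% drug_library()
    i <- match(drug, lib$name)
    if (is.na(i)) stop("unknown drug: ", drug)
    drug <- lib[i, , drop = FALSE]
  }
  if (is.data.frame(drug)) {
    if (nrow(drug) != 1) stop("drug must be a single library row")
    drug <- as.list(drug)
  }
  drug
}

#' Apply a drug to a set of conductance scalings
#'
#' Multiplies each drug-target current's factor by the pore-block
#' remaining-conductance factor at `multiple` times the compound's EFTPC.
#' Currents without a library entry (infinite IC50) and INaL are unchanged.
#' Pure function: the input scaling is not modified. Note the composition
#' contract: applying a drug at c1 then c2 multiplies factors and is not
#' equivalent to a single application at c1 + c2.
#'
#' @param scaling [conductance_scaling()].
#' @param drug A library row, a named list, or a drug name looked up in
#'   `lib`.
#' @param multiple Concentration as a multiple of EFTPC (> 0; 0 is a no-op).
#' @param lib Optional [drug_library()] for name lookup.
#' @return New `conductance_scaling`.
#' @export
apply_drug <- function(scaling, drug, multiple, lib = NULL) {
  g <- as_scaling(scaling)
  if (multiple < 0) stop("multiple must be >= 0")
  drug <- as_drug_record(drug, lib)
  conc <- multiple * drug$eftpc
  for (cur in DRUG_CURRENTS) {
    g[cur] <- g[cur] * block_factor(conc, drug[[paste0(cur, "_ic50")]],
                                    drug[[paste0(cur, "_n")]])
  }
  class(g) <- "conductance_scaling"
  g
}

#' Concentration grid as multiples of EFTPC
#'
#' @param multiples Strictly increasing positive multiples; the study grid
#'   is 1x, 3x, 10x, 30x and 100x EFTPC.
#' @return Numeric vector.
#' @export
concentration_grid <- function(multiples = c(1, 3, 10, 30, 100)) {
  if (any(multiples <= 0) || any(diff(multiples) <= 0))
    stop("multiples must be strictly increasing and positive")
  multiples
}
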