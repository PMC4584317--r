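# Tabular interchange: TSV, UTF-8, mandatory header, "NA" missing token.
# Sex coding 1 = male, 2 = female (FAM convention); binary traits 1 = case.

PEDIGREE_COLS <- c("family_id", "individual_id", "father_id", "mother_id",
                   "sex", "role")
ROLE_CODES <- c("father", "mother", "MZ1", "MZ2", "DZ1", "DZ2", "sib")

#' Read and validate a pedigree file
#'
#' FAM-style TSV extended with a `role` (zygosity) column. Mandatory
#' columns: `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`
#' (1 = male, 2 = female), `role` (`father`, `mother`, `MZ1`, `MZ2`,
#' `DZ1`, `DZ2`, `sib`); unknown columns are preserved. Structural
#' violations (unresolvable parent ids, sex-discordant MZ pairs, families
#' larger than 6) are collected into a `violations` attribute (tibble with
#' `line`, `rule`, `message`) and raised as a single warning rather than
#' failing at the first record; missing mandatory columns or duplicated
#' individual ids are hard parse errors.
#'
#' @param path TSV path.
#' @return A tibble of pedigree records with a `violations` attribute.
#' @export
read_pedigree <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    family_id = "c", individual_id = "c", father_id = "c",
    mother_id = "c", sex = "i", role = "c", .default = "?"),
    na = "NA", progress = FALSE)
  missing_cols <- setdiff(PEDIGREE_COLS, names(d))
  if (length(missing_cols)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "kinliab_parse_error")
  }
  if (anyDuplicated(d$individual_id)) {
    abort(sprintf("duplicated individual id: %s",
                  d$individual_id[duplicated(d$individual_id)][1]),
          class = "kinliab_parse_error")
  }
  viol <- list()
  note <- function(line, rule, msg) {
    viol[[length(viol) + 1]] <<- tibble(line = line, rule = rule,
                                        message = msg)
  }
  bad_role <- !d$role %in% ROLE_CODES
  for (i in which(bad_role)) {
    note(i + 1L, "role",
         sprintf("unknown role/zygosity code '%s' for %s",
                 d$role[i], d$individual_id[i]))
  }
  if (any(bad_role)) {
    abort(paste0("unknown role/zygosity code(s): ",
                 paste(unique(d$role[bad_role]), collapse = ", ")),
          class = "kinliab_parse_error")
  }
  bad_sex <- !is.na(d$sex) & !d$sex %in% 1:2
  for (i in which(bad_sex)) {
    note(i + 1L, "sex", sprintf("sex code %s for %s (expected 1/2)",
                                d$sex[i], d$individual_id[i]))
  }
  for (col in c("father_id", "mother_id")) {
    unresolved <- !is.na(d[[col]]) & !(d[[col]] %in% d$individual_id)
    for (i in which(unresolved)) {
      note(i + 1L, "parent_id",
           sprintf("%s '%s' of %s does not resolve", col, d[[col]][i],
                   d$individual_id[i]))
    }
  }
  by_fam <- split(seq_len(nrow(d)), d$family_id)
  for (rows in by_fam) {
    if (length(rows) > 6) {
      note(rows[1] + 1L, "family_size",
           sprintf("family %s has %d members (max 6 for modelling)",
                   d$family_id[rows[1]], length(rows)))
    }
    mz <- rows[d$role[rows] %in% c("MZ1", "MZ2")]
    if (length(mz) == 2 && length(unique(d$sex[mz])) > 1) {
      note(mz[1] + 1L, "mz_sex",
           sprintf("MZ pair in family %s has discordant sex",
                   d$family_id[mz[1]]))
    }
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble(line = integer(), rule = character(), message = character())
  if (nrow(violations) > 0) {
    warn(sprintf("%d pedigree validation issue(s); see attr(x, 'violations').",
                 nrow(violations)), class = "kinliab_validation_warning")
  }
  attr(d, "violations") <- violations
  d
}

#' Write a pedigree TSV
#' @param pedigree Tibble with the pedigree columns.
#' @param path Output path.
#' @export
write_pedigree <- function(pedigree, path) {
  stopifnot(all(PEDIGREE_COLS %in% names(pedigree)))
  readr::write_tsv(pedigree, path, na = "NA")
  invisible(path)
}

#' Read and validate a phenotype file
#'
#' TSV with mandatory `individual_id`; binary trait columns coded
#' `{0, 1, NA}`; optional `age` (years; values outside 14-80 are flagged,
#' not rejected) and covariates (`pc1`..`pc3`). Violations are collected
#' into a `violations` attribute as for [read_pedigree()].
#'
#' @param path TSV path.
#' @return A tibble with a `violations` attribute.
#' @export
read_phenotypes <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = "c", .default = "?"), na = "NA", progress = FALSE)
  if (!"individual_id" %in% names(d)) {
    abort("missing mandatory column: individual_id",
          class = "kinliab_parse_error")
  }
  if (anyDuplicated(d$individual_id)) {
    abort(sprintf("duplicated individual id: %s",
                  d$individual_id[duplicated(d$individual_id)][1]),
          class = "kinliab_parse_error")
  }
  viol <- list()
  if ("age" %in% names(d)) {
    out_of_range <- which(!is.na(d$age) & (d$age < 14 | d$age > 80))
    for (i in out_of_range) {
      viol[[length(viol) + 1]] <- tibble(
        line = i + 1L, rule = "age_range",
        message = sprintf("age %.1f for %s outside 14-80",
                          d$age[i], d$individual_id[i]))
    }
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble(line = integer(), rule = character(), message = character())
  if (nrow(violations) > 0) {
    warn(sprintf("%d phenotype validation issue(s); see attr(x, 'violations').",
                 nrow(violations)), class = "kinliab_validation_warning")
  }
  attr(d, "violations") <- violations
  d
}

#' Write a phenotype TSV
#' @param phenotypes Tibble with at least `individual_id`.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot("individual_id" %in% names(phenotypes))
  readr::write_tsv(phenotypes, path, na = "NA")
  invisible(path)
}

HAIR_CATEGORIES <- c("fair/blond", "light brown", "red/auburn",
                     "dark brown", "black")

#' Recode raw five-category hair colour into the five binary traits
#'
#' From the raw self-report categories (`fair/blond`, `light brown`,
#' `red/auburn`, `dark brown`, `black`) builds the binary classifications
#' analysed throughout: `blond`, `brown` (light plus dark brown collapsed
#' into a single category), `red`, `black`, and `light_vs_dark` (blond or
#' red versus brown or black - the eumelanin/pheomelanin switch). Exactly
#' one of blond/brown/red/black is 1 for every scored individual; missing
#' raw values give missing traits.
#'
#' @param data Tibble with the raw hair-colour column.
#' @param column Name of that column.
#' @return `data` with the five binary trait columns appended.
#' @export
#' @examples
#' recode_traits(tibble::tibble(hair_color = c("dark brown", "red/auburn", NA)))
recode_traits <- function(data, column = "hair_color") {
  stopifnot(column %in% names(data))
  raw <- data[[column]]
  unknown <- setdiff(unique(raw[!is.na(raw)]), HAIR_CATEGORIES)
  if (length(unknown)) {
    abort(paste0("unknown hair-colour categor",
                 if (length(unknown) > 1) "ies: " else "y: ",
                 paste(unknown, collapse = ", ")),
          class = "kinliab_parse_error")
  }
  data$blond <- as.integer(raw == "fair/blond")
  data$brown <- as.integer(raw %in% c("light brown", "dark brown"))
  data$brown[is.na(raw)] <- NA_integer_
  data$red <- as.integer(raw == "red/auburn")
  data$black <- as.integer(raw == "black")
  data$light_vs_dark <- as.integer(raw %in% c("fair/blond", "red/auburn"))
  data$light_vs_dark[is.na(raw)] <- NA_integer_
  data
}

# Table-1-style correlation table: Classification, Prevalence, then the 13
# r columns in canonical order.
COR_TABLE_COLS <- c("Classification", "Prevalence",
                    paste0("r", c("Spouse", "FS", "FD", "MS", "MD", "MZM",
                                  "MZF", "DZM", "DZF", "DOS", "BB", "SS",
                                  "BS")))

#' Read/write a familial correlation table
#'
#' The interchange layout has one row per trait classification with its
#' prevalence and the 13 pair-class correlations (columns
#' `Classification`, `Prevalence`, `rSpouse`, `rFS`, ..., `rBS`).
#'
#' @param path TSV path.
#' @return `read_correlation_table()`: a tibble in that layout.
#'   `correlation_table_row()`: one classification converted to a
#'   [family_correlations()] object.
#' @export
read_correlation_table <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    Classification = "c", .default = "d"), na = "NA", progress = FALSE)
  missing_cols <- setdiff(COR_TABLE_COLS, names(d))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "kinliab_parse_error")
  }
  d
}

#' @rdname read_correlation_table
#' @param table A correlation table tibble.
#' @export
write_correlation_table <- function(table, path) {
  stopifnot(all(COR_TABLE_COLS %in% names(table)))
  readr::write_tsv(table[, COR_TABLE_COLS], path, na = "NA")
  invisible(path)
}

#' @rdname read_correlation_table
#' @param classification Row label to extract.
#' @param n_pairs Optional named pair counts (as [default_pair_counts()])
#'   to attach as weights.
#' @export
correlation_table_row <- function(table, classification, n_pairs = NULL) {
  row <- table[table$Classification == classification, ]
  if (nrow(row) != 1) {
    abort(sprintf("classification '%s' not found.", classification),
          class = "kinliab_parse_error")
  }
  r <- as.numeric(row[, COR_TABLE_COLS[-(1:2)]])
  family_correlations(
    class = PAIR_CLASSES, r = r,
    n_pairs = if (is.null(n_pairs)) NA_real_ else
      unname(n_pairs[PAIR_CLASSES]),
    prevalence = row$Prevalence, trait = classification
  )
}

#' Convert a fam-cor table back to the interchange layout
#' @param obs A [family_correlations()] tibble.
#' @keywords internal
#' @export
as_correlation_table_row <- function(obs) {
  r <- setNames(rep(NA_real_, 13), PAIR_CLASSES)
  r[obs$class] <- obs$r
  out <- tibble(Classification = attr(obs, "trait") %||% "trait",
                Prevalence = attr(obs, "prevalence"))
  for (i in seq_along(PAIR_CLASSES)) {
    out[[COR_TABLE_COLS[i + 2]]] <- unname(r[i])
  }
  out
}

#' Write a variance-components fit report
#'
#' One row per fitted classification with the assortment coefficient M,
#' the per-sex components and the per-sex heritabilities (columns
#' `Classification`, `M`, `Am`, `Dm/Cm`, `Em`, `Af`, `Df/Cf`, `Ef`,
#' `h2m`, `h2f`).
#'
#' @param fits A named list of `kinliab_fit` objects (names = trait
#'   labels).
#' @param path Output TSV path.
#' @export
write_fit_report <- function(fits, path) {
  rows <- purrr::imap(fits, function(f, nm) {
    vc <- f$estimates
    h2 <- heritability(vc, f$spec)
    tibble(Classification = nm, M = vc$mu,
           Am = vc$Am, `Dm/Cm` = vc$Dm + vc$Cm, Em = vc$Em,
           Af = vc$Af, `Df/Cf` = vc$Df + vc$Cf, Ef = vc$Ef,
           h2m = h2$h2[1], h2f = h2$h2[2])
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, na = "NA")
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' Lines of `key = value` (or `key: value`); `#` comments and blank lines
#' ignored. Values are parsed as logical/numeric where unambiguous.
#'
#' @param path Config path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3) {
      abort(sprintf("cannot parse config line: '%s'", ln),
            class = "kinliab_parse_error")
    }
    key <- trimws(m[2]); val <- trimws(m[3])
    parsed <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(parsed)) parsed
      else if (tolower(val) %in% c("true", "false", "on", "off"))
        tolower(val) %in% c("true", "on")
      else val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
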