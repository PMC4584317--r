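#' Assemble a familial correlation table
#'
#' Light-weight constructor for the per-pair-class correlation table used by
#' [fit_wls()]: one row per relative-pair class (see [pair_classes()]) with
#' the tetrachoric correlation and, optionally, its SE and the number of
#' pairs.
#'
#' @param class Pair-class labels (subset of [pair_classes()]).
#' @param r Correlations in `[-1, 1]`.
#' @param se Optional standard errors.
#' @param n_pairs Optional pair counts.
#' @param prevalence Optional trait prevalence, stored as an attribute.
#' @param trait Optional trait label, stored as an attribute.
#' @return A tibble of class `kinliab_fam_cor`.
#' @export
family_correlations <- function(class, r, se = NA_real_, n_pairs = NA_real_,
                                prevalence = NA_real_, trait = NA_character_) {
  bad <- setdiff(class, PAIR_CLASSES)
  if (length(bad)) {
    abort(paste0("unknown pair class(es): ", paste(bad, collapse = ", ")),
          class = "kinliab_parse_error")
  }
  if (any(abs(r) > 1, na.rm = TRUE)) {
    abort("correlations must lie in [-1, 1].", class = "kinliab_domain_error")
  }
  out <- tibble(class = class, r = r, se = se, n_pairs = n_pairs)
  attr(out, "prevalence") <- prevalence
  attr(out, "trait") <- trait
  class(out) <- c("kinliab_fam_cor", class(out))
  out
}

sex_of <- function(sex) {
  # accepts 1/2 (FAM convention) or "m"/"f"
  if (is.numeric(sex)) c("m", "f")[sex] else tolower(substr(sex, 1, 1))
}

KID_ROLES <- c("MZ1", "MZ2", "DZ1", "DZ2", "sib")

# Enumerate relative pairs from a pedigree-with-phenotype table.
# Returns a tibble (class, y1, y2): member 1 of ordered classes is the
# parent (PO), the male (spouse, DOS, BS), or the first-listed member.
enumerate_pairs <- function(data, trait, twins_in_sib_classes = FALSE) {
  stopifnot(all(c("family_id", "individual_id", "role", "sex") %in% names(data)),
            trait %in% names(data))
  bad <- setdiff(unique(data$role), c("father", "mother", KID_ROLES))
  if (length(bad)) {
    abort(paste0("unknown role/zygosity code(s): ",
                 paste(bad, collapse = ", ")),
          class = "kinliab_parse_error")
  }
  d <- tibble(
    family_id = data$family_id,
    id = data$individual_id,
    role = data$role,
    sex = sex_of(data$sex),
    y = data[[trait]]
  )
  d <- d[!is.na(d$y), ]
  pick <- function(role) d[d$role %in% role, ]
  join2 <- function(d1, d2) {
    out <- dplyr::inner_join(d1, d2, by = "family_id",
                             suffix = c("1", "2"), relationship = "many-to-many")
    out[is.na(out$id1) | is.na(out$id2) | out$id1 != out$id2, ]
  }
  pairs <- list()
  # spouses: member 1 = father (male)
  sp <- join2(pick("father"), pick("mother"))
  pairs$spouse <- tibble(class = rep("spouse", nrow(sp)), y1 = sp$y1, y2 = sp$y2)

  # parent-offspring: member 1 = parent
  kids <- pick(KID_ROLES)
  for (p in c("father", "mother")) {
    po <- join2(pick(p), kids)
    cl <- paste0(ifelse(p == "father", "F", "M"),
                 ifelse(po$sex2 == "m", "S", "D"))
    pairs[[p]] <- tibble(class = cl, y1 = po$y1, y2 = po$y2)
  }

  # twin pairs
  for (z in c("MZ", "DZ")) {
    tw <- join2(pick(paste0(z, "1")), pick(paste0(z, "2")))
    if (nrow(tw) == 0) next
    same <- tw$sex1 == tw$sex2
    cl <- ifelse(same, paste0(z, ifelse(tw$sex1 == "m", "M", "F")), "DOS")
    # DOS ordered male first
    swap <- !same & tw$sex1 == "f"
    y1 <- ifelse(swap, tw$y2, tw$y1)
    y2 <- ifelse(swap, tw$y1, tw$y2)
    pairs[[z]] <- tibble(class = cl, y1 = y1, y2 = y2)
  }

  # sibling classes: sib-sib pairs and twin-sib pairs; twin-twin pairs are
  # counted as twin classes, not sibling classes, unless asked for.
  sibs <- pick("sib")
  ss <- join2(sibs, sibs)
  ss <- ss[ss$id1 < ss$id2, ]
  ts <- join2(pick(KID_ROLES[KID_ROLES != "sib"]), sibs)
  sib_pairs <- dplyr::bind_rows(ss, ts)
  if (twins_in_sib_classes) {
    for (z in c("MZ", "DZ")) {
      tw <- join2(pick(paste0(z, "1")), pick(paste0(z, "2")))
      sib_pairs <- dplyr::bind_rows(sib_pairs, tw)
    }
  }
  if (nrow(sib_pairs) > 0) {
    same <- sib_pairs$sex1 == sib_pairs$sex2
    cl <- ifelse(same, ifelse(sib_pairs$sex1 == "m", "BB", "SS"), "BS")
    swap <- !same & sib_pairs$sex1 == "f" # brother first in BS
    y1 <- ifelse(swap, sib_pairs$y2, sib_pairs$y1)
    y2 <- ifelse(swap, sib_pairs$y1, sib_pairs$y2)
    pairs$sib <- tibble(class = cl, y1 = y1, y2 = y2)
  }
  dplyr::bind_rows(pairs)
}

#' Familial tetrachoric correlations from pedigree data
#'
#' Resolves a pedigree-with-phenotypes table into the 13 relative-pair
#' classes, builds the 2x2 pair table for each class, and estimates one
#' tetrachoric correlation per class ([estimate_tetrachoric()]). Classes
#' with fewer than 2 scored pairs are reported as missing; boundary
#' estimates (e.g. when all phenotypes agree) are flagged in the `boundary`
#' column, never silently dropped.
#'
#' @param data A tibble with columns `family_id`, `individual_id`, `role`
#'   (`father`, `mother`, `MZ1`, `MZ2`, `DZ1`, `DZ2`, `sib`), `sex`
#'   (1 = male, 2 = female), and the binary trait column. The output of
#'   [simulate_families()] or of joining [read_pedigree()] and
#'   [read_phenotypes()] works directly.
#' @param trait Name of the binary trait column.
#' @param twins_in_sib_classes If `TRUE`, twin-twin pairs also contribute to
#'   the sibling classes (`BB`/`SS`/`BS`); by default they do not (sibling
#'   classes use sib-sib and twin-sib pairs only).
#' @return A [family_correlations()] tibble with one row per pair class
#'   (columns `class`, `r`, `se`, `n_pairs`, `boundary`), with the overall
#'   trait prevalence as an attribute.
#' @export
pair_correlation_table <- function(data, trait,
                                   twins_in_sib_classes = FALSE) {
  pr <- enumerate_pairs(data, trait, twins_in_sib_classes)
  prevalence <- mean(data[[trait]], na.rm = TRUE)
  est <- purrr::map(PAIR_CLASSES, function(cl) {
    p <- pr[pr$class == cl, ]
    if (nrow(p) < 2) {
      return(tibble(class = cl, r = NA_real_, se = NA_real_,
                    n_pairs = nrow(p), boundary = NA))
    }
    tab <- contingency_2x2(sum(p$y1 == 1 & p$y2 == 1),
                           sum(p$y1 == 1 & p$y2 == 0),
                           sum(p$y1 == 0 & p$y2 == 1),
                           sum(p$y1 == 0 & p$y2 == 0))
    e <- withCallingHandlers(
      estimate_tetrachoric(tab),
      kinliab_boundary_warning = function(w) invokeRestart("muffleWarning")
    )
    tibble(class = cl, r = e$r, se = e$se, n_pairs = e$n_pairs,
           boundary = isTRUE(e$boundary))
  })
  out <- dplyr::bind_rows(est)
  res <- family_correlations(out$class, out$r, out$se, out$n_pairs,
                             prevalence = prevalence, trait = trait)
  res$boundary <- out$boundary
  res
}

#' Reconstructed pair counts for the Dutch twin-family hair-colour cohort
#'
#' Approximate numbers of scored pairs per relative-pair class, derived from
#' the published cohort composition (N = 20,142 in 7497 families: twin
#' individuals MZM 2345, MZF 4651, DZM 1678, DZF 2710, DOS 3975; 2774
#' parents, i.e. ~1387 couples; 2008 additional siblings). Twin-pair counts
#' are half the individual counts; parent-offspring pairs assume ~1387
#' two-parent families with ~2.16 children each, split equally over the four
#' sex combinations; sibling-class pairs are predominantly twin-sib pairs
#' (2 per sibling), split by the cohort's twin sex ratio. These counts are
#' the natural weights when refitting models to the published correlation
#' table, which prints no per-class SEs.
#'
#' @return A named numeric vector over [pair_classes()].
#' @export
default_pair_counts <- function() {
  c(spouse = 1387,
    FS = 1500, FD = 1500, MS = 1500, MD = 1500,
    MZM = 1172, MZF = 2325, DZM = 839, DZF = 1355, DOS = 1987,
    BB = 810, SS = 1265, BS = 2075)
}
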