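#' Assemble the three predictor blocks for a target
#'
#' Three nested predictor blocks are compared per binary target: `M0`, the
#' five preoperative clinical baseline variables (age, sex, imaging tumor
#' size, biopsy grade, biopsy Ki-67); `MA = M0 +` Family A signatures;
#' `MB = M0 +` Family B delta-signatures. For the higher-grade target
#' (G2/G3 at biopsy) biopsy grade is removed from the baseline (functional
#' status is swapped in to keep five variables) and every signature whose
#' formula contains biopsy grade (A3, A4, A7, B3) is excluded to avoid
#' label leakage.
#'
#' @param target `"progression"` or `"higher_grade"`.
#' @return List of three `block_spec` lists: `name`, `target`,
#'   `clinical_vars`, `signature_vars`, `variables`, `exclusions`.
#' @export
assemble_blocks <- function(target = c("progression", "higher_grade")) {
  target <- match.arg(target)
  if (target == "progression") {
    clinical <- c("age", "sex", "size_cm", "grade_numeric", "ki67_pct")
    fam_a <- paste0("A", 1:7)
    fam_b <- paste0("B", 1:3)
    excl <- character(0)
  } else {
    clinical <- c("age", "sex", "size_cm", "functional", "ki67_pct")
    excl <- c("A3", "A4", "A7", "B3")
    fam_a <- setdiff(paste0("A", 1:7), excl)
    fam_b <- setdiff(paste0("B", 1:3), excl)
  }
  mk <- function(name, sigs) {
    structure(list(name = name, target = target, clinical_vars = clinical,
                   signature_vars = sigs,
                   variables = c(clinical, sigs), exclusions = excl),
              class = "block_spec")
  }
  list(M0 = mk("M0", character(0)),
       MA = mk("MA", fam_a),
       MB = mk("MB", fam_b))
}

#' Build the modeling table for a block target
#'
#' Joins the cohort's clinical variables with the signature panel and
#' defines the binary outcome column `y`: progression status, or the
#' higher-grade indicator (biopsy G2/G3). Sex is encoded 0/1. Rows with a
#' missing outcome are dropped.
#'
#' @param cohort Cohort tibble.
#' @param signatures Signature tibble.
#' @param target `"progression"` or `"higher_grade"`.
#' @return Tibble with `patient_id`, `center`, `y`, and all block variables.
#' @export
assemble_model_data <- function(cohort, signatures,
                                target = c("progression", "higher_grade")) {
  target <- match.arg(target)
  d <- dplyr::left_join(cohort, signatures, by = "patient_id")
  d$sex <- as.integer(d$sex == "male")
  d$y <- if (target == "progression") {
    as.integer(d$progression)
  } else {
    as.integer(d$grade_numeric >= 2)
  }
  d <- d[!is.na(d$y), ]
  keep <- c("patient_id", "center", "y",
            unique(unlist(lapply(assemble_blocks(target),
                                 function(b) b$variables))))
  d[, intersect(keep, names(d))]
}
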