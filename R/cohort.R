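#' Cohort table and descriptive statistics
#'
#' Loaders and summaries for the 50-patient awake-surgery cohort fixture:
#' demographics, lesion histology, peri-acquisition anxiety and
#' self-estimated task-success scores (visual analogue scales, 0-10).
#'
#' @name cohort
NULL

#' Path to a shipped fixture
#'
#' @param name File name under the package's `extdata`.
#' @return Absolute path.
#' @export
lang_fixture <- function(name) {
  p <- system.file("extdata", name, package = "langmapr")
  if (p == "") stop("fixture not found: ", name)
  p
}

#' Load the cohort table
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return Data frame of patient records; missing scores stay `NA`.
#' @export
load_cohort <- function(path = lang_fixture("table1_cohort.csv")) {
  df <- utils::read.csv(path)
  expected <- c("patient", "sex", "age", "lesion_side", "lesion_location",
                "histology", "language_disturbance", "anxiety", "success")
  if (!identical(names(df), expected))
    stop("cohort schema mismatch; offending columns: ",
         paste(union(setdiff(names(df), expected),
                     setdiff(expected, names(df))), collapse = ", "))
  if (nrow(df) == 0) stop("empty cohort file")
  if (anyDuplicated(df$patient)) stop("duplicated patient id(s)")
  stopifnot(all(df$sex %in% c("M", "F")),
            all(df$language_disturbance %in% c("No", "Mild", "Severe")),
            all(is.na(df$anxiety) | (df$anxiety >= 0 & df$anxiety <= 10)),
            all(is.na(df$success) | (df$success >= 0 & df$success <= 10)))
  df
}

#' Histology category of a lesion
#'
#' Codes map to glial / metastasis / nontumoral following the series' own
#' grouping: GB, AA, OA, OD, PA, XA, AB, GG and GS are glial (GB, GS and
#' WHO grade III high-grade, the rest low-grade); lung adenocarcinoma
#' metastases are metastasis; cavernoma, arteriovenous malformation, DNET
#' and radionecrosis are grouped as nontumoral brain lesions (DNET included
#' there despite being a tumour histologically).
#'
#' @param histology Character vector of histology codes.
#' @return Data frame with `category` and `grade` (`high`/`low`/`NA`).
#' @export
histology_category <- function(histology) {
  code <- sub(" .*$", "", histology)
  glial <- c("GB", "AA", "OA", "OD", "PA", "XA", "AB", "GG", "GS")
  category <- ifelse(code %in% glial, "glial",
                     ifelse(grepl("metastasis", histology, ignore.case = TRUE),
                            "metastasis", "nontumoral"))
  grade <- rep(NA_character_, length(histology))
  is_g <- category == "glial"
  grade[is_g] <- ifelse(code[is_g] %in% c("GB", "GS") |
                          grepl("III", histology[is_g]), "high", "low")
  data.frame(category = category, grade = grade)
}

#' Descriptive cohort summary
#'
#' Means and SDs (n - 1 denominator) over non-missing values; counts by sex,
#' language disturbance and histology category. Missing scores are excluded
#' listwise per variable, never imputed.
#'
#' @param records Cohort data frame from [load_cohort()].
#' @return List of summary statistics.
#' @export
summarize_cohort <- function(records) {
  stopifnot(nrow(records) >= 1)
  msd <- function(x) {
    x <- x[!is.na(x)]
    list(mean = mean(x), sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
         n = length(x))
  }
  hc <- histology_category(records$histology)
  list(n = nrow(records),
       n_male = sum(records$sex == "M"),
       n_female = sum(records$sex == "F"),
       age = msd(records$age),
       anxiety = msd(records$anxiety),
       success = msd(records$success),
       n_language_disturbance = sum(records$language_disturbance != "No"),
       histology = as.list(table(hc$category)),
       glial_grades = as.list(table(hc$grade[hc$category == "glial"])))
}

#' Welch t test against a reference cohort known only by summaries
#'
#' @param x Numeric scores of the study cohort (NAs dropped).
#' @param ref_mean,ref_sd,ref_n Summary statistics of the reference cohort
#'   (`ref_n >= 2`).
#' @return List: `t`, `df` (Welch-Satterthwaite), `p` (two-sided),
#'   `direction` (sign of study minus reference).
#' @export
compare_to_reference <- function(x, ref_mean, ref_sd, ref_n) {
  stopifnot(ref_n >= 2)
  x <- x[!is.na(x)]
  n1 <- length(x)
  m1 <- mean(x)
  v1 <- stats::var(x)
  v2 <- ref_sd^2
  se2 <- v1 / n1 + v2 / ref_n
  if (se2 > 0) {
    t <- (m1 - ref_mean) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / ref_n)^2 / (ref_n - 1))
    p <- 2 * stats::pt(-abs(t), df = df)
  } else {  # degenerate: both samples constant
    t <- if (m1 == ref_mean) 0 else Inf * sign(m1 - ref_mean)
    df <- Inf
    p <- if (m1 == ref_mean) 1 else 0
  }
  list(t = t, df = df, p = p, direction = sign(m1 - ref_mean))
}
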