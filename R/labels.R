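#' Covariate label coding
#'
#' Age is treated as a categorical variable with one class per integer year of
#' the inclusion range (16 classes for the default 22-37 range); sex has the
#' fixed class order (M, F). Both are one-hot encoded for the supervised heads
#' of the autoencoder.
#'
#' @param age_range Inclusive integer age range.
#' @param sex_classes Class order for sex; fixed default `c("M", "F")`.
#' @return A `label_coding` list with `age_classes` and `sex_classes`.
#' @export
label_coding <- function(age_range = c(22L, 37L), sex_classes = c("M", "F")) {
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2])
  structure(list(age_classes = seq.int(age_range[1], age_range[2]),
                 sex_classes = sex_classes),
            class = "label_coding")
}

#' One-hot encode age and sex
#'
#' @param table A `morphometry_table`.
#' @param coding A `label_coding`.
#' @return List with `age` (subjects x n_age_classes) and `sex`
#'   (subjects x 2) one-hot matrices; every row sums to exactly 1.
#' @export
encode_labels <- function(table, coding = label_coding()) {
  age_idx <- match(table$age, coding$age_classes)
  if (anyNA(age_idx)) {
    stop("age(s) outside the label coding: ",
         paste(unique(table$age[is.na(age_idx)]), collapse = ", "))
  }
  sex_idx <- match(table$sex, coding$sex_classes)
  if (anyNA(sex_idx)) stop("sex value outside the label coding")
  n <- nrow(table)
  age <- matrix(0, n, length(coding$age_classes),
                dimnames = list(table$subject_id, coding$age_classes))
  age[cbind(seq_len(n), age_idx)] <- 1
  sex <- matrix(0, n, length(coding$sex_classes),
                dimnames = list(table$subject_id, coding$sex_classes))
  sex[cbind(seq_len(n), sex_idx)] <- 1
  list(age = age, sex = sex)
}
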