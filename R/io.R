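#' Read a NIfTI-1 volume
#'
#' Loads a 3-D or 4-D NIfTI image, reorienting the data to the canonical RAS
#' axis order when the header carries a different orientation; the original
#' orientation string is recorded in attribute `"original_orientation"`.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param mask if TRUE, return a logical mask array.
#' @return numeric (or logical) array with attributes `voxel_size` and,
#'   for 4-D images, `tr`.
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  orig <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  hdr <- RNifti::niftiHeader(img)
  reorientable <- hdr$qform_code > 0 || hdr$sform_code > 0
  if (reorientable && !is.na(orig) && nzchar(orig) && orig != "RAS")
    RNifti::orientation(img) <- "RAS"
  pd <- RNifti::pixdim(img)
  d <- dim(img)
  out <- array(as.numeric(img), dim = d)
  if (mask) out <- array(out != 0, dim = d)
  attr(out, "voxel_size") <- abs(pd[seq_len(min(3, length(pd)))])
  if (length(d) == 4L)
    attr(out, "tr") <- hdr$pixdim[5]
  attr(out, "original_orientation") <- orig
  out
}

#' Write a NIfTI-1 volume
#'
#' Images are written in canonical RAS orientation with a diagonal qform.
#'
#' @param x 3-D or 4-D array (logical masks are written as 0/1).
#' @param path output file.
#' @param voxel_size voxel edge lengths in mm.
#' @param tr repetition time in s (4-D images).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = c(3, 3, 3), tr = NULL) {
  d <- dim(x)
  if (is.logical(x) || is.integer(x)) x <- array(as.numeric(x), dim = d)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- if (length(d) == 4L) c(voxel_size, tr %||% 1) else voxel_size
  img <- RNifti::`qform<-`(img, structure(diag(c(voxel_size, 1)), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and validate a phenotype table
#'
#' Tab-separated, one row per subject, with columns subject_id, group,
#' pair_id, age, sex, lesion_side, lesion_frac and the raw cognitive scores
#' `score_*_raw`. Validates the patient-control pairing (each patient's pair
#' id must match exactly one control) and adds z-scored columns
#' (`score_*_z`, population-SD standardization) when absent.
#'
#' @param path TSV file.
#' @return data.frame of class `phenotypes`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(ph)
}

#' @rdname read_phenotypes
#' @param ph a phenotype data.frame (e.g. `cohort$subjects`).
#' @export
validate_phenotypes <- function(ph) {
  required <- c("subject_id", "group", "pair_id", "age", "sex",
                "lesion_side", "lesion_frac")
  missing <- setdiff(required, names(ph))
  if (length(missing))
    stop_thalcor("phenotype table lacks columns: ",
                 paste(missing, collapse = ", "),
                 class = "thalcor_validation_error")
  if (!all(ph$group %in% c("patient", "control")))
    stop_thalcor("group must be 'patient' or 'control'",
                 class = "thalcor_validation_error")
  if (any(ph$lesion_frac < 0 | ph$lesion_frac >= 1))
    stop_thalcor("lesion fraction must lie in [0, 1)",
                 class = "thalcor_validation_error")
  pats <- ph[ph$group == "patient", ]
  cons <- ph[ph$group == "control", ]
  if (anyDuplicated(cons$pair_id))
    stop_thalcor("duplicate pair id among controls: ",
                 paste(unique(cons$pair_id[duplicated(cons$pair_id)]),
                       collapse = ", "),
                 class = "thalcor_validation_error")
  unmatched <- setdiff(pats$pair_id, cons$pair_id)
  if (length(unmatched))
    stop_thalcor("patients without a matched control: pair ids ",
                 paste(unmatched, collapse = ", "),
                 class = "thalcor_validation_error")
  raw_cols <- grep("^score_.*_raw$", names(ph), value = TRUE)
  for (rc in raw_cols) {
    if (!is.numeric(ph[[rc]]))
      stop_thalcor("non-numeric score column ", rc,
                   class = "thalcor_validation_error")
    zc <- sub("_raw$", "_z", rc)
    if (!zc %in% names(ph)) ph[[zc]] <- scale_z(ph[[rc]])
  }
  class(ph) <- c("phenotypes", "data.frame")
  ph
}

## z-score with population (1/n) standard deviation
scale_z <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Pairing table from a phenotype table
#'
#' @param ph a phenotype data.frame.
#' @return data.frame with columns patient, control, pair_id.
#' @export
phenotype_pairing <- function(ph) {
  pats <- ph[ph$group == "patient", c("subject_id", "pair_id")]
  cons <- ph[ph$group == "control", c("subject_id", "pair_id")]
  m <- merge(pats, cons, by = "pair_id", suffixes = c("_patient", "_control"))
  data.frame(patient = m$subject_id_patient, control = m$subject_id_control,
             pair_id = m$pair_id, stringsAsFactors = FALSE)
}

#' Synthetic recruitment roster
#'
#' A 29-row roster emulating the recruitment flow of a paediatric stroke
#' cohort: candidates carry flags for the four exclusion rules (bilateral
#' lesion, imaging artefact, sequence error, compliance problems) with the
#' default counts 4, 1, 2 and 2, leaving 20 eligible subjects.
#'
#' @param n roster size.
#' @param n_bilateral,n_artefact,n_sequence_error,n_noncompliant counts per
#'   exclusion reason.
#' @param seed seed for shuffling the roster order.
#' @return data.frame with candidate_id and the four logical flag columns.
#' @export
synthetic_roster <- function(n = 29, n_bilateral = 4, n_artefact = 1,
                             n_sequence_error = 2, n_noncompliant = 2,
                             seed = 1) {
  n_excl <- n_bilateral + n_artefact + n_sequence_error + n_noncompliant
  if (n_excl > n)
    stop_thalcor("exclusion counts exceed the roster size",
                 class = "thalcor_validation_error")
  flags <- c(rep("bilateral", n_bilateral), rep("artefact", n_artefact),
             rep("sequence_error", n_sequence_error),
             rep("noncompliant", n_noncompliant),
             rep("none", n - n_excl))
  set.seed(seed)
  flags <- sample(flags)
  data.frame(candidate_id = sprintf("R%02d", seq_len(n)),
             bilateral_lesion = flags == "bilateral",
             imaging_artefact = flags == "artefact",
             sequence_error = flags == "sequence_error",
             noncompliant = flags == "noncompliant",
             stringsAsFactors = FALSE)
}

#' Apply the recruitment exclusion rules to a roster
#'
#' Excludes candidates with bilateral lesions, imaging (retainer) artefacts,
#' anatomical/BOLD sequence errors, or compliance problems, and tallies the
#' exclusions per rule.
#'
#' @param roster data.frame from [synthetic_roster()] (or with the same flag
#'   columns).
#' @return list with `included` (data.frame of retained rows), `n_included`,
#'   and `excluded` (named counts per rule).
#' @export
filter_roster <- function(roster) {
  rules <- c("bilateral_lesion", "imaging_artefact", "sequence_error",
             "noncompliant")
  missing <- setdiff(rules, names(roster))
  if (length(missing))
    stop_thalcor("roster lacks flag columns: ", paste(missing, collapse = ", "),
                 class = "thalcor_validation_error")
  excl <- vapply(rules, function(r) sum(roster[[r]]), integer(1))
  drop <- Reduce(`|`, roster[rules])
  included <- roster[!drop, , drop = FALSE]
  list(included = included, n_included = nrow(included), excluded = excl)
}
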