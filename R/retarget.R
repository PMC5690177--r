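# Plan retargeting: reuse the best-matching template plan for a new
# patient. Only patient identity, the unique plan identifier and the
# isocenter change; beams, MLC settings and monitor units are preserved
# verbatim. Prescription dose is deliberately left untouched (entered in
# the treatment planning system when dose is recomputed).

#' Retarget a template plan to a new patient
#'
#' The ICP translation maps the patient's anatomy onto the database
#' case's frame, so template geometry is carried back into the patient
#' frame by the inverse translation: the new isocenter is
#' \code{template isocenter - icpTranslation}. A fresh SOP instance UID
#' is generated; every beam attribute is kept identical.
#'
#' @param template the matched [PlanTemplate-class].
#' @param newPatientName,newPatientID identity of the new patient.
#' @param icpTranslation numeric(3) mm, the translation returned by
#'   [icpAlign()] / [rankDatabase()] (patient to database frame).
#' @return A new [PlanTemplate-class].
#' @examples
#' pl <- planTemplate("CASE_001", "DB001", c(0, 0, 5),
#'                    beams = list(list(gantry_angle_deg = 90)))
#' new <- retargetPlan(pl, "NEW^PATIENT", "NP001", c(10, 0, -5))
#' planIsocenter(new)  # c(-10, 0, 10)
#' @export
retargetPlan <- function(template, newPatientName, newPatientID,
                         icpTranslation = c(0, 0, 0)) {
  validObject(template)
  if (length(icpTranslation) != 3L || !all(is.finite(icpTranslation)))
    stop("ICP translation must be 3 finite values", call. = FALSE)
  if (length(template@isocenter) != 3L ||
      !all(is.finite(template@isocenter)))
    stop("template plan has no usable isocenter", call. = FALSE)
  new("PlanTemplate",
      patientName = as.character(newPatientName),
      patientID = as.character(newPatientID),
      planLabel = template@planLabel,
      sopInstanceUID = freshUID(),
      isocenter = template@isocenter - as.numeric(icpTranslation),
      beams = template@beams,
      extra = template@extra)
}

#' Attribute-level difference between two plans
#'
#' Compares every top-level plan attribute (identity, label, UID,
#' isocenter, beams, pass-through block) and reports which differ; used
#' to verify that retargeting changes nothing but patient identity, the
#' unique identifier and the isocenter. Numeric attributes are compared
#' to 1e-9 relative tolerance (file round trips preserve doubles to the
#' serializer's precision, not bitwise).
#'
#' @param a,b [PlanTemplate-class] objects.
#' @return Character vector of differing attribute names (possibly
#'   empty).
#' @export
planDiff <- function(a, b) {
  slots <- c("patientName", "patientID", "planLabel", "sopInstanceUID",
             "isocenter", "beams", "extra")
  differs <- vapply(slots, function(s) {
    !isTRUE(all.equal(slot(a, s), slot(b, s), tolerance = 1e-9))
  }, TRUE)
  slots[differs]
}
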