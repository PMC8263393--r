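## Recognized ACMG/AMP evidence codes.
.acmg_codes <- c("PVS1",
                 paste0("PS", 1:4),
                 paste0("PM", 1:6),
                 paste0("PP", 1:5),
                 "BA1",
                 paste0("BS", 1:4),
                 paste0("BP", 1:7))

#' Combine ACMG evidence criteria into a pathogenicity classification
#'
#' Applies the standard ACMG/AMP combining rules to a set of evidence codes
#' (PVS1, PS1-PS4, PM1-PM6, PP1-PP5, BA1, BS1-BS4, BP1-BP7).  The label
#' depends only on the per-strength counts.  When both a pathogenic-side
#' and a benign-side rule match, the evidence is contradictory and the
#' variant is of uncertain significance.
#'
#' @param codes character vector of evidence codes (a set; duplicates are
#'   ignored).
#' @return list with \code{label} (one of Pathogenic, Likely pathogenic,
#'   Uncertain significance, Likely benign, Benign) and \code{matched_rule}.
#' @export
#' @examples
#' combine_criteria(c("PVS1", "PS2", "PM2", "PP3"))$label  # "Pathogenic"
#' combine_criteria(c("PS3", "PM2", "PP3", "PP4"))$label   # "Likely pathogenic"
combine_criteria <- function(codes) {
  codes <- unique(as.character(codes))
  bad <- setdiff(codes, .acmg_codes)
  if (length(bad))
    stop("unknown ACMG code(s): ", paste(bad, collapse = ", "))
  n <- c(pvs = sum(codes == "PVS1"),
         ps = sum(grepl("^PS", codes)),
         pm = sum(grepl("^PM", codes)),
         pp = sum(grepl("^PP", codes)),
         ba = sum(codes == "BA1"),
         bs = sum(grepl("^BS", codes)),
         bp = sum(grepl("^BP", codes)))

  path_rule <- if (n["pvs"] >= 1 && n["ps"] >= 1) "PVS1 + >=1 PS"
  else if (n["pvs"] >= 1 && n["pm"] >= 2) "PVS1 + >=2 PM"
  else if (n["pvs"] >= 1 && n["pm"] == 1 && n["pp"] >= 1) "PVS1 + 1 PM + 1 PP"
  else if (n["pvs"] >= 1 && n["pp"] >= 2) "PVS1 + >=2 PP"
  else if (n["ps"] >= 2) ">=2 PS"
  else if (n["ps"] == 1 && n["pm"] >= 3) "1 PS + >=3 PM"
  else if (n["ps"] == 1 && n["pm"] == 2 && n["pp"] >= 2) "1 PS + 2 PM + >=2 PP"
  else if (n["ps"] == 1 && n["pm"] == 1 && n["pp"] >= 4) "1 PS + 1 PM + >=4 PP"
  else NULL

  lp_rule <- if (n["pvs"] >= 1 && n["pm"] == 1) "PVS1 + 1 PM"
  else if (n["ps"] == 1 && n["pm"] >= 1 && n["pm"] <= 2) "1 PS + 1-2 PM"
  else if (n["ps"] == 1 && n["pp"] >= 2) "1 PS + >=2 PP"
  else if (n["pm"] >= 3) ">=3 PM"
  else if (n["pm"] == 2 && n["pp"] >= 2) "2 PM + >=2 PP"
  else if (n["pm"] == 1 && n["pp"] >= 4) "1 PM + >=4 PP"
  else NULL

  benign_rule <- if (n["ba"] >= 1) "BA1"
  else if (n["bs"] >= 2) ">=2 BS"
  else NULL

  lb_rule <- if (n["bs"] == 1 && n["bp"] >= 1) "1 BS + 1 BP"
  else if (n["bp"] >= 2) ">=2 BP"
  else NULL

  patho_side <- if (!is.null(path_rule)) list("Pathogenic", path_rule)
  else if (!is.null(lp_rule)) list("Likely pathogenic", lp_rule)
  else NULL
  benign_side <- if (!is.null(benign_rule)) list("Benign", benign_rule)
  else if (!is.null(lb_rule)) list("Likely benign", lb_rule)
  else NULL

  if (!is.null(patho_side) && !is.null(benign_side))
    return(list(label = "Uncertain significance",
                matched_rule = "conflicting pathogenic and benign evidence"))
  if (!is.null(patho_side))
    return(list(label = patho_side[[1]], matched_rule = patho_side[[2]]))
  if (!is.null(benign_side))
    return(list(label = benign_side[[1]], matched_rule = benign_side[[2]]))
  list(label = "Uncertain significance", matched_rule = "no rule matched")
}
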