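## Independent rule-table oracle: each combining rule is written out as an
## explicit count requirement and scanned flatly, unlike the package's
## nested short-circuit logic.
acmg_oracle <- function(codes) {
  codes <- unique(codes)
  nPVS <- sum(codes == "PVS1"); nPS <- length(grep("^PS", codes))
  nPM <- length(grep("^PM", codes)); nPP <- length(grep("^PP", codes))
  nBA <- sum(codes == "BA1"); nBS <- length(grep("^BS", codes))
  nBP <- length(grep("^BP", codes))
  path <- (nPVS >= 1 && (nPS >= 1 || nPM >= 2 || (nPM == 1 && nPP >= 1) ||
                           nPP >= 2)) ||
    nPS >= 2 ||
    (nPS == 1 && (nPM >= 3 || (nPM == 2 && nPP >= 2) || (nPM == 1 && nPP >= 4)))
  lp <- (nPVS >= 1 && nPM == 1) ||
    (nPS == 1 && nPM >= 1 && nPM <= 2) ||
    (nPS == 1 && nPP >= 2) ||
    nPM >= 3 ||
    (nPM == 2 && nPP >= 2) ||
    (nPM == 1 && nPP >= 4)
  ben <- nBA >= 1 || nBS >= 2
  lb <- (nBS == 1 && nBP >= 1) || nBP >= 2
  p_side <- if (path) "Pathogenic" else if (lp) "Likely pathogenic" else NA
  b_side <- if (ben) "Benign" else if (lb) "Likely benign" else NA
  if (!is.na(p_side) && !is.na(b_side)) return("Uncertain significance")
  if (!is.na(p_side)) return(p_side)
  if (!is.na(b_side)) return(b_side)
  "Uncertain significance"
}
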