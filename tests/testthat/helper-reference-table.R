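# Reference values (4 dp) for the median/min/max true outside-probability
# by expected-count range, for all three limit methods at the 95% and
# 99.8% levels.  Used as the regression anchor for coverage_table().
reference_coverage_table <- function() {
  cell <- function(level, tail, method, range, median, min, max) {
    data.frame(level = level, tail = tail, method = method, range = range,
               median = median, min = min, max = max,
               stringsAsFactors = FALSE)
  }
  ranges <- c("1-50", ">50-100", ">100-500", ">500-1000", ">1000-10000")
  triples <- list(
    # level, tail, method -> 5 ranges x (median, min, max)
    list(0.95, "lower", "wald", rbind(
      c(0.0184, 0, 0.0250), c(0.0216, 0.0172, 0.0251), c(0.0233, 0.0194, 0.0251),
      c(0.0240, 0.0225, 0.0251), c(0.0246, 0.0232, 0.0250))),
    list(0.95, "lower", "exact", rbind(
      c(0.0325, 0.0219, 0.3679), c(0.0287, 0.0248, 0.0351), c(0.0267, 0.0248, 0.0317),
      c(0.0261, 0.0249, 0.0277), c(0.0254, 0.0250, 0.0269))),
    list(0.95, "lower", "prediction", rbind(
      c(0.0186, 0, 0.0250), c(0.0215, 0.0172, 0.0250), c(0.0233, 0.0194, 0.0250),
      c(0.0239, 0.0224, 0.0250), c(0.0246, 0.0232, 0.0250))),
    list(0.95, "upper", "wald", rbind(
      c(0.0301, 0.0203, 0.0841), c(0.0280, 0.0247, 0.0331), c(0.0266, 0.0248, 0.0307),
      c(0.0260, 0.0249, 0.0275), c(0.0254, 0.0249, 0.0268))),
    list(0.95, "upper", "exact", rbind(
      c(0.0121, 0.0003, 0.0177), c(0.0166, 0.0129, 0.0196), c(0.0203, 0.0157, 0.0225),
      c(0.0220, 0.0203, 0.0232), c(0.0238, 0.0216, 0.0244))),
    list(0.95, "upper", "prediction", rbind(
      c(0.0201, 0.0052, 0.0250), c(0.0220, 0.0184, 0.0250), c(0.0234, 0.0200, 0.0250),
      c(0.0240, 0.0226, 0.0250), c(0.0246, 0.0233, 0.0250))),
    list(0.998, "lower", "wald", rbind(
      c(0.0002, 0, 0.0006), c(0.0005, 0.0003, 0.0007), c(0.0007, 0.0005, 0.0009),
      c(0.0008, 0.0007, 0.0009), c(0.0009, 0.0008, 0.0010))),
    list(0.998, "lower", "exact", rbind(
      c(0.0028, 0.0016, 0.3679), c(0.0017, 0.0014, 0.0026), c(0.0013, 0.0012, 0.0020),
      c(0.0012, 0.0011, 0.0013), c(0.0011, 0.0010, 0.0012))),
    list(0.998, "lower", "prediction", rbind(
      c(0.0006, 0, 0.0010), c(0.0008, 0.0006, 0.0010), c(0.0009, 0.0007, 0.0010),
      c(0.0009, 0.0009, 0.0010), c(0.0010, 0.0009, 0.0010))),
    list(0.998, "upper", "wald", rbind(
      c(0.0021, 0.0014, 0.0133), c(0.0016, 0.0013, 0.0021), c(0.0013, 0.0011, 0.0018),
      c(0.0011, 0.0011, 0.0013), c(0.0011, 0.0010, 0.0012))),
    list(0.998, "upper", "exact", rbind(
      c(0.0002, 0.0000, 0.0004), c(0.0004, 0.0002, 0.0005), c(0.0006, 0.0004, 0.0007),
      c(0.0007, 0.0006, 0.0008), c(0.0009, 0.0007, 0.0009))),
    list(0.998, "upper", "prediction", rbind(
      c(0.0007, 0.0002, 0.0010), c(0.0008, 0.0007, 0.0010), c(0.0009, 0.0007, 0.0010),
      c(0.0009, 0.0009, 0.0010), c(0.0010, 0.0009, 0.0010)))
  )
  out <- do.call(rbind, lapply(triples, function(tr) {
    do.call(rbind, lapply(1:5, function(b) {
      cell(tr[[1]], tr[[2]], tr[[3]], ranges[b],
           tr[[4]][b, 1], tr[[4]][b, 2], tr[[4]][b, 3])
    }))
  }))
  rownames(out) <- NULL
  out
}
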