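# Independent literal transcription of the classification flowchart, kept
# deliberately naive for truth-table comparison against classify_curves().
flowchart_reference <- function(upper, lower, us, ls) {
  any_above <- upper > 10 || lower > 10
  if (!any_above) return("no_scoliosis")
  both_above <- upper > 10 && lower > 10
  if (!both_above) {
    if (upper > lower) return("thoracic") else return("lumbar")
  }
  if (us != ls) "thoracolumbar" else "combined"
}

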