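# shared fixtures, built in code
default_lex <- build_default_lexicon()

# the printed ordinal scales, transcribed independently of feature_scales()
printed_scales <- data.frame(
  feature_id = c(rep("ANGULATION", 4), rep("ROOT_COUNT", 3),
                 rep("ROOT_CURVATURE", 3), rep("CANAL_RELATION", 4)),
  category = c("Mesioangular", "Horizontal", "Vertical", "Distoangular",
               "Single fused root", "Two roots", "Three or more roots",
               "Incomplete roots", "Straight roots", "Dilacerated roots",
               "No contact", "Approximation", "Contact", "Inside"),
  score = c(1, 2, 3, 4, 1, 2, 3, 1, 2, 3, 1, 2, 3, 4),
  stringsAsFactors = FALSE
)
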