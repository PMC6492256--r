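#' The complex 18-scene target language
#'
#' Builds the experimenter-designed target language for the full-language
#' learning experiments: three-word descriptions (quantifier, noun, verb),
#' each word a transparent stem plus a suffix that redundantly marks number,
#' with lexically conditioned irregularities. Quantifiers take `-a`/`-ak`
#' for singular/plural except with crocodiles (`-u`/`-uk`); nouns take
#' `-o`/`-op` except the bird, whose plural is also `-o`; verbs take
#' `-an`/`-asp` (duck, bird) or `-en`/`-esp` (crocodile), except that every
#' plural looping scene takes `-onk`.
#'
#' @return A [language_spec()] over the 18-scene set with word classes
#'   Q, N, V.
#' @examples
#' render_description(build_exp1_target(),
#'                    list(number = "two", animal = "crocodile", motion = "loop"))
#' @export
build_exp1_target <- function() {
  scenes <- scene_grid(1)
  q_stem <- c(one = "won", two = "sum")
  n_stem <- c(duck = "kwak", bird = "twit", crocodile = "snap")
  v_stem <- c(straight = "woosh", bounce = "boing", loop = "loop")

  q_suffix <- function(number, animal) {
    if (animal == "crocodile") c(one = "u", two = "uk")[[number]]
    else c(one = "a", two = "ak")[[number]]
  }
  n_suffix <- function(number, animal) {
    if (number == "one" || animal == "bird") "o" else "op"
  }
  v_suffix <- function(number, animal, motion) {
    if (number == "two" && motion == "loop") return("onk")
    if (animal == "crocodile") c(one = "en", two = "esp")[[number]]
    else c(one = "an", two = "asp")[[number]]
  }

  rows <- do.call(rbind, lapply(seq_len(nrow(scenes)), function(i) {
    nu <- as.character(scenes$number[i])
    an <- as.character(scenes$animal[i])
    mo <- as.character(scenes$motion[i])
    data.frame(number = nu, animal = an, motion = mo,
               class = c("Q", "N", "V"),
               stem = c(q_stem[[nu]], n_stem[[an]], v_stem[[mo]]),
               suffix = c(q_suffix(nu, an), n_suffix(nu, an), v_suffix(nu, an, mo)),
               stringsAsFactors = FALSE)
  }))
  language_spec(c("Q", "N", "V"), rows, experiment = 1,
                meta = list(language = "complex_target"))
}
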