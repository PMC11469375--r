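# small shared fixtures, built in code at test time

quiet_vowel <- function(...) synth_vowel(vowel_spec(...))$recording

# a canonical short vowel used by several files
test_vowel <- function(seed = 1, duration = 0.4, ...) {
  quiet_vowel(f0 = 120, duration = duration, seed = seed, ...)
}

sine_recording <- function(freq, amp = 0.2, duration = 0.5, rate = 16000) {
  audio_recording(amp * sin(2 * pi * freq * seq(0, duration, by = 1 / rate)),
                  rate)
}
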