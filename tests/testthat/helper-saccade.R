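# Synthetic saccade trace: smooth raised-cosine pulse peaking at `peak_ms`
# after the question, on top of optional white noise, split antisymmetric
# across the two electrodes.
saccade_trace <- function(peak_ms, amp, sfreq = 250, dur_s = 5,
                          question_s = 1, width_ms = 200, noise_sd = 0,
                          seed = 1) {
  withr::with_seed(seed, {
    n <- dur_s * sfreq
    t_ms <- (seq_len(n) - 1) / sfreq * 1000 - question_s * 1000
    pulse <- ifelse(abs(t_ms - peak_ms) < width_ms / 2,
                    0.5 * (1 + cos(2 * pi * (t_ms - peak_ms) / width_ms)),
                    0)
    list(left = rnorm(n, sd = noise_sd) - amp / 2 * pulse,
         right = rnorm(n, sd = noise_sd) + amp / 2 * pulse)
  })
}
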