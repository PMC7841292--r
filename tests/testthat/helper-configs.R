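## Shared small network configurations for the unit tests.
smallConfig <- function(depth = 4L, input = 16L, kernel = 3L, seed = 1L)
  networkConfig(inputShape = c(input, input),
                layers = list(convLayerSpec(kernel, depth)), seed = seed)
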