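{
  "colour_terms": ["black", "blue", "brown", "green", "grey", "orange", "pink", "purple", "red", "turquoise", "white", "yellow"],
  "emotion_terms": ["admiration", "amusement", "anger", "compassion", "contempt", "contentment", "disappointment", "disgust", "fear", "guilt", "hate", "interest", "joy", "love", "pleasure", "pride", "regret", "relief", "sadness", "shame"],
  "countries": ["CN", "DE", "GB", "GR"]
}
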