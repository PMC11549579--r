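{
  "loneliness": {
    "label": ["1=low", "5=moderate", "10=high"],
    "text": [
      "Take care everyone. Thanks for the great talk.",
      "I went on Monday and today. After today's class is when I felt worse as I chatted with a lady in class who told me that she got really depressed when she retired.",
      "I just always feel totally alone. Like no one understands what is going on in my head."
    ]
  },
  "optimism": {
    "label": ["1=positive", "0=neutral", "-1=negative"],
    "text": [
      "I am optimistic that I might slowly get better.",
      "I didn't do much today. Just stayed at home and watched some TV.",
      "Feeling so overwhelmed by everything. It's hard to see a way out right now."
    ]
  }
}
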