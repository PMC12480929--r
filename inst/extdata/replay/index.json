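[
  {
    "id": "heart_claude_v1",
    "prompt_hash": "3347c4fde666911c1a60095fd37064ca",
    "file": "heart_claude_v1_synthetic.txt",
    "provenance": "claude-opus (synthetic replay fixture)"
  },
  {
    "id": "heart_chatgpt_v1",
    "prompt_hash": "d1fbff360aed7dffee13998fbc2b4b4f",
    "file": "heart_chatgpt_v1_synthetic.txt",
    "provenance": "chatgpt-4o-mini (synthetic replay fixture)"
  },
  {
    "id": "concrete_gemini_v1",
    "prompt_hash": "c8e921cae7fa0bf10a2f3d3e56e68ac1",
    "file": "concrete_gemini_v1_synthetic.txt",
    "provenance": "gemini-2.5-pro (synthetic replay fixture)"
  }
]
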