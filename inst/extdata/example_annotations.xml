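<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic example exam in the package's minimal annotation dialect:
     two readers annotated the same exam; the reader that identified the
     most lesions is the one the pipeline keeps. -->
<annotations exam="synthetic-example-001">
  <reader id="reader-A">
    <nodule id="A1">
      <center z="41" y="210" x="155"/>
      <diameter_mm>8.5</diameter_mm>
      <malignancy>2</malignancy>
      <solid>true</solid>
    </nodule>
    <nodule id="A2">
      <center z="57" y="118" x="301"/>
      <diameter_mm>14.0</diameter_mm>
      <malignancy>4</malignancy>
      <solid>true</solid>
    </nodule>
    <nodule id="A3">
      <center z="72" y="330" x="204"/>
      <diameter_mm>5.2</diameter_mm>
      <malignancy>1</malignancy>
      <solid>false</solid>
    </nodule>
  </reader>
  <reader id="reader-B">
    <nodule id="B1">
      <center z="41" y="212" x="154"/>
      <diameter_mm>8.9</diameter_mm>
      <malignancy>2</malignancy>
      <solid>true</solid>
    </nodule>
    <nodule id="B2">
      <center z="57" y="117" x="300"/>
      <diameter_mm>13.6</diameter_mm>
      <malignancy>5</malignancy>
      <solid>true</solid>
    </nodule>
    <nodule id="B3">
      <center z="71" y="331" x="206"/>
      <diameter_mm>5.0</diameter_mm>
      <malignancy>1</malignancy>
      <solid>false</solid>
    </nodule>
    <nodule id="B4">
      <center z="88" y="240" x="260"/>
      <diameter_mm>3.4</diameter_mm>
      <malignancy>3</malignancy>
      <solid>true</solid>
    </nodule>
    <nodule id="B5">
      <center z="95" y="199" x="180"/>
      <diameter_mm>22.0</diameter_mm>
      <malignancy>4</malignancy>
      <solid>true</solid>
    </nodule>
  </reader>
</annotations>
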